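#' Meiosis I parameters
#'
#' Parameters of the meiosis I segregation model. All rates are per-meiosis
#' probabilities at the level of whole-chromosome (reductional) segregation;
#' chromatids are not modelled.
#'
#' @param p_nonexchange_X probability that an exchange-competent X pair fails
#'   to cross over (spontaneous nonexchange; classically 5-10 percent of
#'   meioses, default 0.075). Balancer heterozygotes block exchange outright,
#'   regardless of this value; for inversion heterozygotes set it high
#'   (e.g. 0.95) to express the suppression.
#' @param p_secondary_ndj convenience alias for `p_hs[["XX|Y"]]`: probability,
#'   given nonexchange Xs and a Y present, that the Xs co-orient away from the
#'   Y (the XX<=>Y secondary nondisjunction pattern).
#' @param p_hs named list of heterologous co-orientation probabilities. Names
#'   are unordered unit pairs joined by `|`, e.g. `"C1|C4"`, `"44|C1"`,
#'   `"C4|XX"`, `"XX|Y"`. Unit tokens: `"XX"` the X pair, `"44"` the free 4
#'   pair, `"Y"` a free or derived Y, otherwise the copy label of a monovalent
#'   compound. Pairs involving `"XX"` apply only in nonexchange meioses.
#'   With probability `1 - sum(applicable p_hs)` no pair engages and every
#'   unit segregates by its default rule.
#' @param p_recombinant probability that the single X transmitted by an
#'   exchange meiosis is recombinant in the scored marker interval (the v-f
#'   span). Used by the simulator only; the analytic gamete distribution
#'   tracks eligibility, not marker state.
#' @param p_monovalent_recovery probability a monovalent is included in the
#'   ovum; fixed at exactly 0.5 (random segregation to either pole).
#' @param seed optional integer seed recorded for simulation runs.
#' @return object of class `meiosis_params`.
#' @examples
#' meiosis_params(p_secondary_ndj = 0.65, p_nonexchange_X = 1)
#' @export
meiosis_params <- function(p_nonexchange_X = 0.075, p_secondary_ndj = NULL,
                           p_hs = list(), p_recombinant = 0,
                           p_monovalent_recovery = 0.5, seed = NULL) {
  if (!identical(p_monovalent_recovery, 0.5))
    stop("p_monovalent_recovery is fixed at exactly 0.5")
  chk01 <- function(x, what) {
    if (!is.numeric(x) || any(x < 0 | x > 1))
      stop(what, " must be a probability in [0, 1]")
  }
  chk01(p_nonexchange_X, "p_nonexchange_X")
  chk01(p_recombinant, "p_recombinant")
  p_hs <- as.list(p_hs)
  if (length(p_hs)) {
    if (is.null(names(p_hs)) || any(!nzchar(names(p_hs))))
      stop("p_hs must be a named list keyed by unit pairs like 'C1|C4'")
    names(p_hs) <- vapply(strsplit(names(p_hs), "|", fixed = TRUE),
                          function(ab) {
                            if (length(ab) != 2L)
                              stop("p_hs keys must name exactly two units, e.g. 'XX|Y'")
                            hs_pair_key(ab[1], ab[2])
                          }, character(1))
    for (nm in names(p_hs)) chk01(p_hs[[nm]], paste0("p_hs[['", nm, "']]"))
  }
  if (!is.null(p_secondary_ndj)) {
    chk01(p_secondary_ndj, "p_secondary_ndj")
    p_hs[[hs_pair_key("XX", "Y")]] <- p_secondary_ndj
  }
  if (anyDuplicated(names(p_hs)))
    stop("duplicate heterolog pair keys in p_hs")
  structure(list(p_nonexchange_X = p_nonexchange_X, p_hs = p_hs,
                 p_recombinant = p_recombinant,
                 p_monovalent_recovery = 0.5, seed = seed),
            class = "meiosis_params")
}

hs_pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' @export
print.meiosis_params <- function(x, ...) {
  cat("<meiosis_params>\n")
  cat(sprintf("  p_nonexchange_X: %g\n", x$p_nonexchange_X))
  for (nm in names(x$p_hs)) cat(sprintf("  p_hs[%s]: %g\n", nm, x$p_hs[[nm]]))
  if (x$p_recombinant > 0) cat(sprintf("  p_recombinant: %g\n", x$p_recombinant))
  invisible(x)
}

## ---- segregation units ------------------------------------------------------

# Decompose a karyotype into the units the segregation model knows how to
# orient: an X pair, a free 4 pair, a Y monovalent, compound monovalents.
# Anything else fails loudly (never silent misclassification).
segregation_units <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  copies <- k$copies
  is_single_X <- vapply(copies, function(cp)
    identical(unname(cp$elements["X"]), 1L) && !("Y" %in% names(cp$elements)) &&
      cp$rearrangement %in% c("normal", "inversion", "balancer"), logical(1))
  is_Y <- vapply(copies, function(cp)
    !is.na(cp$elements["Y"]) && cp$elements["Y"] >= 1L &&
      !("X" %in% names(cp$elements)), logical(1))
  is_four <- vapply(copies, function(cp)
    identical(unname(cp$elements["4"]), 1L) && cp$rearrangement == "normal",
    logical(1))
  is_compound <- vapply(copies, function(cp)
    cp$rearrangement == "compound", logical(1))
  claimed <- is_single_X | is_Y | is_four | is_compound
  if (!all(claimed))
    stop("unsupported karyotype configuration: cannot classify copy '",
         names(copies)[which(!claimed)[1]], "'")

  units <- list()
  nX <- sum(is_single_X)
  if (nX == 2L) {
    xs <- copies[is_single_X]
    units <- c(units, list(list(
      token = "XX", kind = "x_pair", copies = xs,
      exchangeable = all(vapply(xs, `[[`, logical(1), "exchange_competent")))))
  } else if (nX != 0L) {
    stop("unsupported karyotype configuration: ", nX,
         " unpaired single X copies (supported: 0 or 2)")
  }
  nY <- sum(is_Y)
  if (nY == 1L) {
    units <- c(units, list(list(token = "Y", kind = "mono",
                                copies = copies[is_Y])))
  } else if (nY != 0L) {
    stop("unsupported karyotype configuration: more than one Y")
  }
  n4 <- sum(is_four)
  if (n4 == 2L) {
    units <- c(units, list(list(token = "44", kind = "four_pair",
                                copies = copies[is_four])))
  } else if (n4 != 0L) {
    stop("unsupported karyotype configuration: ", n4,
         " free 4 copies (supported: 0 or 2)")
  }
  for (cp in copies[is_compound]) {
    units <- c(units, list(list(token = cp$label, kind = "mono",
                                copies = list(cp))))
  }
  tokens <- vapply(units, `[[`, character(1), "token")
  if (anyDuplicated(tokens))
    stop("unsupported karyotype configuration: duplicated unit tokens")
  names(units) <- tokens
  units
}

# Which configured heterolog pairs can apply to this unit set, split by
# whether they require a nonexchange X pair.
applicable_hs_pairs <- function(units, p_hs) {
  tokens <- names(units)
  keep <- vapply(names(p_hs), function(key) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    all(ab %in% tokens)
  }, logical(1))
  p_hs <- p_hs[keep]
  needs_nonexchange <- vapply(names(p_hs), function(key)
    "XX" %in% strsplit(key, "|", fixed = TRUE)[[1]], logical(1))
  list(conditional = p_hs[needs_nonexchange],
       unconditional = p_hs[!needs_nonexchange])
}

## ---- gamete distribution ----------------------------------------------------

# class key for an ovum content (multiset of copy labels)
ovum_key <- function(labels) {
  if (!length(labels)) "none" else paste(sort(labels), collapse = "+")
}

#' Exact gamete class distribution
#'
#' Computes the analytic (not sampled) probability distribution over ovum
#' content classes for a supported karyotype. Segregation logic: an exchange X
#' bivalent sends homologs to opposite poles; nonexchange Xs with a configured
#' heterologous partner co-orient away from it (both Xs together) with the
#' pair's probability, otherwise disjoin from each other with the partner
#' segregating at random; two heterologous monovalents co-orient to opposite
#' poles with their pair probability and otherwise segregate independently
#' (so a pair probability of zero is the independence null, a quarter of ova
#' with both chromosomes and a quarter with neither); a lone monovalent enters
#' the ovum with probability exactly 0.5; a free 4 pair disjoins unless
#' engaged by a partner.
#'
#' @param k a [karyotype()].
#' @param p a [meiosis_params()].
#' @return object of class `gamete_distribution`: ovum classes (multisets of
#'   copy labels), their probabilities (summing to one within 1e-12), and for
#'   each class the fraction of its probability arising from an exchange
#'   meiosis transmitting a single X (used to place recombinants).
#' @examples
#' k <- karyotype_preset("C1C4")
#' gamete_distribution(k, meiosis_params(p_hs = list("C1|C4" = 0)))
#' @export
gamete_distribution <- function(k, p = meiosis_params()) {
  stopifnot(inherits(p, "meiosis_params"))
  units <- segregation_units(k)
  acc <- new.env(parent = emptyenv())
  add <- function(labels, prob, exch_x) {
    if (prob <= 0) return(invisible())
    key <- ovum_key(labels)
    cur <- acc[[key]]
    if (is.null(cur)) cur <- list(labels = sort(labels), prob = 0, prob_exch = 0)
    cur$prob <- cur$prob + prob
    if (exch_x) cur$prob_exch <- cur$prob_exch + prob
    acc[[key]] <- cur
  }

  unit_labels <- function(u) {
    unlist(lapply(u$copies, `[[`, "label"), use.names = FALSE)
  }
  # default segregation outcomes of one unit: list of (labels, prob, exch_x)
  default_outcomes <- function(u, x_status) {
    if (u$kind == "x_pair") {
      labs <- vapply(u$copies, `[[`, character(1), "label")
      eligible <- identical(x_status, "exchange")
      list(list(labels = labs[1], prob = 0.5, exch_x = eligible),
           list(labels = labs[2], prob = 0.5, exch_x = eligible))
    } else if (u$kind == "four_pair") {
      list(list(labels = "4", prob = 1, exch_x = FALSE))
    } else {
      labs <- unit_labels(u)
      list(list(labels = labs, prob = 0.5, exch_x = FALSE),
           list(labels = character(), prob = 0.5, exch_x = FALSE))
    }
  }
  emit <- function(rest, weight, base_labels, exch_x, x_status) {
    if (!length(rest)) {
      add(base_labels, weight, exch_x)
      return(invisible())
    }
    outs <- default_outcomes(rest[[1]], x_status)
    for (o in outs)
      emit(rest[-1], weight * o$prob, c(base_labels, o$labels),
           exch_x || o$exch_x, x_status)
  }
  engaged_sides <- function(pair_key) {
    ab <- strsplit(pair_key, "|", fixed = TRUE)[[1]]
    lapply(ab, function(tok) {
      u <- units[[tok]]
      if (u$kind %in% c("x_pair", "four_pair")) unit_labels(u) else unit_labels(u)
    })
  }

  has_xx <- "XX" %in% names(units)
  branches <- if (!has_xx) {
    list(list(status = "none", w = 1))
  } else if (units[["XX"]]$exchangeable) {
    list(list(status = "exchange", w = 1 - p$p_nonexchange_X),
         list(status = "nonexchange", w = p$p_nonexchange_X))
  } else {
    list(list(status = "nonexchange", w = 1))
  }

  for (br in branches) {
    if (br$w <= 0) next
    pairs <- applicable_hs_pairs(units, p$p_hs)
    active <- pairs$unconditional
    if (identical(br$status, "nonexchange")) active <- c(active, pairs$conditional)
    qsum <- if (length(active)) sum(unlist(active)) else 0
    if (qsum > 1 + 1e-12)
      stop("applicable heterologous pair probabilities sum to more than 1")
    for (key in names(active)) {
      q <- active[[key]]
      if (q <= 0) next
      sides <- engaged_sides(key)
      tok <- strsplit(key, "|", fixed = TRUE)[[1]]
      rest <- units[setdiff(names(units), tok)]
      for (s in 1:2)
        emit(rest, br$w * q * 0.5, sides[[s]], FALSE, br$status)
    }
    if (qsum < 1)
      emit(units, br$w * (1 - qsum), character(), FALSE, br$status)
  }

  keys <- ls(acc)
  probs <- vapply(keys, function(kk) acc[[kk]]$prob, numeric(1))
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  ord <- order(-probs, keys)
  keys <- keys[ord]; probs <- probs[ord]
  structure(list(
    classes = stats::setNames(lapply(keys, function(kk) acc[[kk]]$labels), keys),
    prob = stats::setNames(probs, keys),
    p_exchange_origin = stats::setNames(
      vapply(keys, function(kk) {
        pr <- acc[[kk]]
        if (pr$prob > 0) pr$prob_exch / pr$prob else 0
      }, numeric(1)), keys),
    karyotype = k, params = p, units = names(units)
  ), class = "gamete_distribution")
}

#' @export
print.gamete_distribution <- function(x, digits = 6, ...) {
  cat(sprintf("<gamete_distribution: %d ovum classes (%s)>\n",
              length(x$prob),
              if (nzchar(x$karyotype$label)) x$karyotype$label else "unlabelled"))
  print(round(x$prob, digits))
  invisible(x)
}

#' Probability of a heterologous biorientation at metaphase I
#'
#' Probability that a configured heterolog pair ends bioriented (the two units
#' at opposite poles) at metaphase I arrest: engagement events always biorient
#' the pair; when both units are monovalents, independent segregation lands
#' them at opposite poles half the time as well. Under the model assumption
#' that metaphase orientation is drawn from the same distribution as
#' segregation, this is also the expected cytological HS configuration rate.
#'
#' @param k a [karyotype()].
#' @param p a [meiosis_params()].
#' @return probability in `[0, 1]` (summed over configured pairs).
#' @export
hs_orientation_prob <- function(k, p) {
  units <- segregation_units(k)
  has_xx <- "XX" %in% names(units)
  branches <- if (!has_xx) list(list(status = "none", w = 1))
  else if (units[["XX"]]$exchangeable)
    list(list(status = "exchange", w = 1 - p$p_nonexchange_X),
         list(status = "nonexchange", w = p$p_nonexchange_X))
  else list(list(status = "nonexchange", w = 1))
  total <- 0
  for (br in branches) {
    if (br$w <= 0) next
    pairs <- applicable_hs_pairs(units, p$p_hs)
    active <- pairs$unconditional
    if (identical(br$status, "nonexchange")) active <- c(active, pairs$conditional)
    qsum <- if (length(active)) sum(unlist(active)) else 0
    total <- total + br$w * qsum
    # residual biorientation of monovalent-monovalent pairs under independence
    for (key in names(active)) {
      tok <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (all(vapply(units[tok], function(u) u$kind == "mono", logical(1))))
        total <- total + br$w * (1 - qsum) * 0.5
    }
  }
  total
}
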