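#' Zygote viability model
#'
#' An ordered list of rules mapping a zygote's element doses to a survival
#' probability; the first matching rule wins and a fully balanced zygote
#' survives with probability 1. The default rule set encodes standard fly
#' genetics for the crosses modelled here: aneuploidy for a major autosome arm
#' (2L, 2R, 3L, 3R dose other than 2) is lethal, as are nullo-X, triplo-X,
#' YY-without-X, nullo-4 and dose >= 4 for chromosome 4; triplo-4 is viable;
#' haplo-4 zygotes survive with probability `v_minute`.
#'
#' `v_minute` doubles as recovery bookkeeping: the haplo-4 "minute" phenotype
#' is so poorly viable that an exceptional minute class is treated as
#' unrecoverable (and its loss compensated by doubling the sister class) when
#' `v_minute = 0`.
#'
#' @param v_minute survival probability of haplo-4 zygotes (default 0).
#' @param rules optional replacement rule list; each rule is a list with
#'   fields `name` and `test` (a function of the named dose vector and the
#'   character vector of tracked elements, returning `TRUE`/`FALSE`) and `p`
#'   (survival probability when the rule matches, or the string `"v_minute"`).
#' @return object of class `viability_model`.
#' @export
viability_model <- function(v_minute = 0, rules = NULL) {
  stopifnot(is.numeric(v_minute), v_minute >= 0, v_minute <= 1)
  if (is.null(rules)) rules <- default_viability_rules()
  structure(list(rules = rules, v_minute = v_minute), class = "viability_model")
}

default_viability_rules <- function() {
  majors <- c("2L", "2R", "3L", "3R")
  list(
    list(name = "major_aneuploid",
         test = function(dose, tracked) {
           m <- intersect(majors, tracked)
           length(m) > 0 && any(dose[m] != 2L)
         }, p = 0),
    list(name = "nullo_X",
         test = function(dose, tracked) "X" %in% tracked && dose["X"] == 0L, p = 0),
    list(name = "triplo_X",
         test = function(dose, tracked) "X" %in% tracked && dose["X"] >= 3L, p = 0),
    list(name = "YY_without_X",
         test = function(dose, tracked) "Y" %in% tracked && dose["Y"] >= 2L &&
           dose["X"] == 0L, p = 0),
    list(name = "nullo_4",
         test = function(dose, tracked) "4" %in% tracked && dose["4"] == 0L, p = 0),
    list(name = "haplo_4_minute",
         test = function(dose, tracked) "4" %in% tracked && dose["4"] == 1L,
         p = "v_minute"),
    list(name = "hyper_4",
         test = function(dose, tracked) dose["4"] >= 4L, p = 0)
  )
}

#' @export
print.viability_model <- function(x, ...) {
  cat(sprintf("<viability_model: %d rules, v_minute = %g>\n",
              length(x$rules), x$v_minute))
  invisible(x)
}

#' Zygote survival probability
#'
#' Applies the viability model's ordered rules to a zygote; the first matching
#' rule determines survival, and a zygote matched by no rule (balanced) has
#' survival 1. Deterministic: the same zygote always gets the same value.
#'
#' @param zygote a zygote from [fertilize()].
#' @param v a [viability_model()].
#' @return survival probability in `[0, 1]`.
#' @examples
#' z <- fertilize(c("X.yw", "X.yw"), "Xp", tracked = c("X", "Y"))
#' survival(z, viability_model())  # triplo-X: 0
#' @export
survival <- function(zygote, v = viability_model()) {
  stopifnot(inherits(zygote, "hs_zygote"), inherits(v, "viability_model"))
  for (rule in v$rules) {
    if (isTRUE(rule$test(zygote$dose, zygote$tracked))) {
      p <- rule$p
      if (identical(p, "v_minute")) p <- v$v_minute
      return(p)
    }
  }
  1
}

## ---- fertilization ----------------------------------------------------------

# label -> elements lookup built from a list of chromosome copies
label_registry <- function(copies) {
  reg <- list()
  for (cp in copies) {
    if (!is.null(reg[[cp$label]])) {
      if (!identical(reg[[cp$label]]$elements, cp$elements))
        stop("conflicting element content for copy label '", cp$label, "'")
    } else reg[[cp$label]] <- cp
  }
  reg
}

#' Fuse an ovum class with a sperm class
#'
#' Zygote element dose is the sum of ovum and sperm doses; copy identities are
#' retained so phenotype classes can be assigned. `tracked` names the elements
#' the cross actually follows; untracked elements are assumed balanced and are
#' ignored by the viability rules.
#'
#' @param ovum character vector of maternal copy labels (may be empty).
#' @param sperm character vector of paternal copy labels (may be empty).
#' @param copies list of [chromosome_copy()] objects resolving the labels
#'   (defaults to the built-in catalog).
#' @param tracked character vector of tracked elements; defaults to the union
#'   of elements carried by the referenced copies.
#' @return object of class `hs_zygote` with fields `dose`, `sex`, `ovum`,
#'   `sperm`, `tracked`.
#' @examples
#' fertilize(c("X.yw", "X.yw"), "Yp")$dose[c("X", "Y")]  # XXY female
#' @export
fertilize <- function(ovum, sperm, copies = copy_catalog(), tracked = NULL) {
  reg <- label_registry(copies)
  resolve <- function(labels) {
    lapply(labels, function(lb) {
      cp <- reg[[lb]]
      if (is.null(cp)) stop("unknown chromosome copy label: '", lb, "'")
      cp
    })
  }
  mo <- resolve(ovum); fa <- resolve(sperm)
  dose <- element_dose(c(mo, fa))
  if (is.null(tracked)) {
    tracked <- unique(unlist(lapply(c(mo, fa), function(cp) names(cp$elements))))
    if (is.null(tracked)) tracked <- character()
  }
  sex <- if (dose["X"] >= 2L) "female" else if (dose["X"] == 1L) "male" else NA_character_
  structure(list(dose = dose, sex = sex,
                 ovum = sort(as.character(ovum)), sperm = sort(as.character(sperm)),
                 tracked = tracked),
            class = "hs_zygote")
}

#' @export
print.hs_zygote <- function(x, ...) {
  dd <- x$dose[x$dose > 0]
  cat(sprintf("<zygote %s x %s | %s | %s>\n",
              ovum_key(x$ovum), ovum_key(x$sperm),
              paste(sprintf("%s:%d", names(dd), dd), collapse = " "),
              if (is.na(x$sex)) "inviable-sex" else x$sex))
  invisible(x)
}

## ---- cross design -----------------------------------------------------------

#' Define a cross between an experimental female and tester males
#'
#' Enumerates every ovum class the female can produce (under a canonical
#' parameterization in which all configured branches occur), crosses each with
#' every sperm class, and builds the class table used for phenotype
#' classification, correction-factor derivation and simulation: survival under
#' the viability model, partition into normal / HS-exceptional / other, and a
#' scored flag. Exceptional classes whose surviving zygotes are haplo-4 minute
#' are marked unscored when `viability$v_minute == 0` (their loss is what the
#' extra doubling compensates); additional ovum classes can be declared
#' unscored explicitly (e.g. products that carry no maternal marker and cannot
#' be attributed in the progeny).
#'
#' @param female the female's [karyotype()].
#' @param sperm_classes list of sperm classes, each
#'   `list(labels = <character>, prob = <numeric>)`; probabilities must sum
#'   to 1.
#' @param hs_pairs character vector of heterolog pair keys active in this
#'   cross (e.g. `"XX|Y"`); see [meiosis_params()].
#' @param partition_fun function mapping an ovum label vector to one of
#'   `"normal"`, `"hs_exceptional"`, `"other"`.
#' @param unscored_ova character vector of ovum class keys never scored.
#' @param viability a [viability_model()].
#' @param label free-text cross label.
#' @return object of class `cross_design`.
#' @export
cross_design <- function(female, sperm_classes, hs_pairs, partition_fun,
                         unscored_ova = character(),
                         viability = viability_model(), label = "") {
  stopifnot(inherits(female, "karyotype"), is.function(partition_fun),
            inherits(viability, "viability_model"))
  probs <- vapply(sperm_classes, `[[`, numeric(1), "prob")
  if (abs(sum(probs) - 1) > 1e-9) stop("sperm class probabilities must sum to 1")
  sperm_keys <- vapply(sperm_classes, function(s) ovum_key(s$labels), character(1))
  if (anyDuplicated(sperm_keys)) stop("duplicate sperm classes")
  names(sperm_classes) <- sperm_keys

  units <- segregation_units(female)  # validates support
  canonical <- canonical_params(units, hs_pairs)
  dist <- gamete_distribution(female, canonical)

  catalog <- copy_catalog()
  registry <- c(unname(female$copies),
                catalog[vapply(catalog, function(cp)
                  cp$label %in% unique(unlist(lapply(sperm_classes, `[[`, "labels"))),
                  logical(1))])
  tracked <- unique(unlist(lapply(registry, function(cp) names(cp$elements))))

  rows <- list()
  for (ok in names(dist$classes)) {
    olabs <- dist$classes[[ok]]
    part <- partition_fun(olabs)
    if (!part %in% c("normal", "hs_exceptional", "other"))
      stop("partition_fun must return 'normal', 'hs_exceptional' or 'other'")
    for (sk in sperm_keys) {
      z <- fertilize(olabs, sperm_classes[[sk]]$labels, registry, tracked)
      surv <- survival(z, viability)
      hard <- survival(z, viability_model(v_minute = 1, rules = viability$rules))
      minute <- "4" %in% tracked && z$dose["4"] == 1L
      scored <- !(ok %in% unscored_ova) &&
        !(part == "hs_exceptional" && minute && viability$v_minute == 0)
      rows[[length(rows) + 1L]] <- data.frame(
        ovum = ok, sperm = sk, ovum_prob = unname(dist$prob[ok]),
        sperm_prob = sperm_classes[[sk]]$prob, partition = part,
        survival = surv, hard_survival = hard, minute = minute,
        scored = scored, stringsAsFactors = FALSE)
    }
  }
  classes <- do.call(rbind, rows)
  classes$label <- paste(classes$ovum, "x", classes$sperm)
  structure(list(female = female, sperm_classes = sperm_classes,
                 hs_pairs = hs_pairs, partition_fun = partition_fun,
                 unscored_ova = unscored_ova, viability = viability,
                 classes = classes, registry = registry, tracked = tracked,
                 canonical_dist = dist, label = label),
            class = "cross_design")
}

# canonical parameterization that realizes every structural branch
canonical_params <- function(units, hs_pairs) {
  q <- if (length(hs_pairs)) 0.5 / length(hs_pairs) else numeric()
  p_hs <- stats::setNames(as.list(rep(q, length(hs_pairs))), hs_pairs)
  meiosis_params(p_nonexchange_X = 0.5, p_hs = p_hs)
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("<cross_design%s>\n",
              if (nzchar(x$label)) paste0(" ", x$label) else ""))
  cat("  female:", x$female$label, "\n")
  cat("  sperm classes:", paste(names(x$sperm_classes), collapse = ", "), "\n")
  cat("  heterolog pairs:", paste(x$hs_pairs, collapse = ", "), "\n")
  tab <- x$classes[x$classes$survival > 0, c("ovum", "sperm", "partition", "scored")]
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Phenotype class of a surviving zygote
#'
#' Looks the zygote up in the cross design's class table. The returned label
#' carries the normal / HS-exceptional / other partition and the scored flag
#' as attributes.
#'
#' @param zygote a zygote from [fertilize()] whose ovum and sperm classes are
#'   drawn from `design`.
#' @param design a [cross_design()].
#' @return character phenotype class label with attributes `partition` and
#'   `scored`.
#' @export
phenotype_class <- function(zygote, design) {
  stopifnot(inherits(zygote, "hs_zygote"), inherits(design, "cross_design"))
  ok <- ovum_key(zygote$ovum); sk <- ovum_key(zygote$sperm)
  row <- design$classes[design$classes$ovum == ok & design$classes$sperm == sk, ]
  if (nrow(row) != 1L)
    stop("zygote class not covered by the cross design marker map: ",
         ok, " x ", sk)
  if (row$survival <= 0)
    stop("phenotype_class is defined only for zygotes with survival > 0: ",
         ok, " x ", sk)
  structure(row$label, partition = row$partition, scored = row$scored)
}

## ---- preset cross designs ---------------------------------------------------

sperm_preset <- function(which) {
  switch(which,
    X_Y_4 = list(list(labels = c("Xp", "4p"), prob = 0.5),
                 list(labels = c("Yp", "4p"), prob = 0.5)),
    X_Y_C4 = list(list(labels = c("Xp", "C4p"), prob = 0.25),
                  list(labels = "Xp", prob = 0.25),
                  list(labels = c("Yp", "C4p"), prob = 0.25),
                  list(labels = "Yp", prob = 0.25)),
    C1YS_C4 = list(list(labels = c("C1YSp", "C4p"), prob = 0.25),
                   list(labels = "C1YSp", prob = 0.25),
                   list(labels = "C4p", prob = 0.25),
                   list(labels = character(), prob = 0.25)),
    C2L_C2R = list(list(labels = c("C2Lp", "C2Rp"), prob = 0.25),
                   list(labels = "C2Lp", prob = 0.25),
                   list(labels = "C2Rp", prob = 0.25),
                   list(labels = character(), prob = 0.25)),
    stop("unknown sperm preset")
  )
}

# partition rules shared by the preset families
partition_xx_vs_partner <- function(x_label_set, partner_label) {
  force(x_label_set); force(partner_label)
  function(labels) {
    n_x <- sum(labels %in% x_label_set)
    if (n_x == 2L) return("hs_exceptional")                # both Xs together
    if (n_x == 0L && partner_label %in% labels) return("hs_exceptional")
    if (n_x == 1L) return("normal")
    "other"                                                # neither X nor partner
  }
}

partition_two_compounds <- function(a, b) {
  force(a); force(b)
  function(labels) {
    n <- (a %in% labels) + (b %in% labels)
    if (n == 1L) "hs_exceptional" else "other"
  }
}

partition_mono_vs_44 <- function(mono) {
  force(mono)
  function(labels) {
    n4 <- sum(labels == "4")
    has_mono <- mono %in% labels
    if ((has_mono && n4 == 0L) || (!has_mono && n4 == 2L)) "hs_exceptional"
    else "normal"
  }
}

#' Built-in cross designs
#'
#' One preset per genotype with genetic (progeny count) data in the packaged
#' tables. The tester males and scoring conventions follow the published
#' crosses: XXY females crossed to marked X / y+Y males with free 4s;
#' X/X; C(4)/0 females to the same; C(1)/0 females to X / y+Y; C(4)/0 males
#' (the 4,4-bearing HS product yields progeny with no maternal marker and is
#' unscored); double-compound females to compound-bearing males, where every
#' scored class suffers the same sperm-genotype loss.
#'
#' @param name one of the presets with genetic data (see [list_presets()];
#'   `C2EN_mono` has none).
#' @param viability a [viability_model()].
#' @return a [cross_design()].
#' @examples
#' correction_factor(cross_preset("XXY_yw"))  # 2
#' @export
cross_preset <- function(name, viability = viability_model()) {
  name <- match.arg(name, setdiff(HS_PRESETS, "C2EN_mono"))
  cc <- copy_catalog()
  switch(name,
    C1_mono = cross_design(
      karyotype_preset("C1_mono"), sperm_preset("X_Y_C4"),
      hs_pairs = hs_pair_key("C1", "44"),
      partition_fun = partition_mono_vs_44("C1"),
      unscored_ova = "4+4", viability = viability,
      label = "C(1)RM / 0 females x y w f / y+Y; C(4)RM / 0 males"),
    C4_mono = cross_design(
      karyotype_preset("C4_mono"), sperm_preset("X_Y_4"),
      hs_pairs = hs_pair_key("XX", "C4"),
      partition_fun = partition_xx_vs_partner("X.ywf", "C4"),
      viability = viability,
      label = "y w f; C(4)RM / 0 females x X / y+Y males"),
    In1_C4 = cross_design(
      karyotype_preset("In1_C4"), sperm_preset("X_Y_4"),
      hs_pairs = hs_pair_key("XX", "C4"),
      partition_fun = partition_xx_vs_partner(c("X.ywf", "In1"), "C4"),
      viability = viability,
      label = "y w f / In(1)dl-49; C(4)RM / 0 females x y w / y+Y males"),
    FM7_C4 = cross_design(
      karyotype_preset("FM7_C4"), sperm_preset("X_Y_4"),
      hs_pairs = hs_pair_key("XX", "C4"),
      partition_fun = partition_xx_vs_partner(c("X.ywf", "FM7"), "C4"),
      viability = viability,
      label = "y w f / FM7; C(4)RM / 0 females x y w / y+Y males"),
    XXY_yw = cross_design(
      karyotype_preset("XXY_yw"), sperm_preset("X_Y_4"),
      hs_pairs = hs_pair_key("XX", "Y"),
      partition_fun = partition_xx_vs_partner("X.yw", "yY"),
      viability = viability,
      label = "y w / y w / y+Y females x marked X / y+Y males"),
    FM7_XXY = cross_design(
      karyotype_preset("FM7_XXY"), sperm_preset("X_Y_4"),
      hs_pairs = hs_pair_key("XX", "Y"),
      partition_fun = partition_xx_vs_partner(c("FM7", "X.yw"), "yY"),
      viability = viability,
      label = "FM7 / y w / y+Y females x marked X / y+Y males"),
    In1_XXY = cross_design(
      karyotype_preset("In1_XXY"), sperm_preset("X_Y_4"),
      hs_pairs = hs_pair_key("XX", "Y"),
      partition_fun = partition_xx_vs_partner(c("In1", "X.ywf"), "Y"),
      viability = viability,
      label = "In(1)dl-49 / y w f / Y females x y w f / y+Y males"),
    C1C4 = cross_design(
      karyotype_preset("C1C4"), sperm_preset("C1YS_C4"),
      hs_pairs = hs_pair_key("C1", "C4"),
      partition_fun = partition_two_compounds("C1", "C4"),
      viability = viability,
      label = "C(1)RM / 0; C(4)RM / 0 females x C(1;YS) / 0; C(4)RM / 0 males"),
    C2L_C2R = cross_design(
      # tracked system reduced to chromosome 2: sex chromosomes and 4s
      # segregate normally in this cross and are carried as balanced background
      karyotype(list(cc[["C2L"]], cc[["C2R"]]), label = "C(2L)RM / 0; C(2R)RM / 0"),
      sperm_preset("C2L_C2R"),
      hs_pairs = hs_pair_key("C2L", "C2R"),
      partition_fun = partition_two_compounds("C2L", "C2R"),
      viability = viability,
      label = "C(2L) / 0; C(2R) / 0 females x C(2L) / 0; C(2R) / 0 males")
  )
}

# study-condition meiosis parameters per preset genotype (the observed rates
# re-expressed as model parameters; see the methods vignette)
preset_params <- function(name) {
  name <- match.arg(name, HS_PRESETS)
  switch(name,
    C1_mono   = meiosis_params(p_hs = list("44|C1" = 0.02)),
    C2EN_mono = meiosis_params(p_hs = list("44|C2EN" = 0.03)),
    C4_mono   = meiosis_params(p_nonexchange_X = 0.075,
                               p_hs = list("C4|XX" = 0.4)),
    In1_C4    = meiosis_params(p_nonexchange_X = 0.95,
                               p_hs = list("C4|XX" = 0.057)),
    FM7_C4    = meiosis_params(p_nonexchange_X = 1,
                               p_hs = list("C4|XX" = 0.075)),
    XXY_yw    = meiosis_params(p_nonexchange_X = 0.075, p_secondary_ndj = 0.5),
    FM7_XXY   = meiosis_params(p_nonexchange_X = 1, p_secondary_ndj = 0.613),
    In1_XXY   = meiosis_params(p_nonexchange_X = 0.95, p_secondary_ndj = 0.688,
                               p_recombinant = 0.12),
    C1C4      = meiosis_params(p_hs = list("C1|C4" = 0.942)),
    C2L_C2R   = meiosis_params(p_hs = list("C2L|C2R" = 0.98))
  )
}

#' Load a cross design from a JSON-compatible configuration
#'
#' Supports `list(preset = "<name>", v_minute = <p>)` or a full specification
#' with `female` (a karyotype config), `sperm_classes`, `hs_pairs`,
#' `partition` (one of `"xx_vs_partner"`, `"two_compounds"`, `"mono_vs_44"`
#' plus its arguments) and optional `unscored_ova` / `v_minute`.
#'
#' @param config a list or path to a JSON file.
#' @return a [cross_design()].
#' @export
cross_design_from_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  v <- viability_model(v_minute = config$v_minute %||% 0)
  if (!is.null(config$preset)) return(cross_preset(config$preset, viability = v))
  female <- karyotype_from_config(config$female)
  sperm <- lapply(config$sperm_classes, function(s)
    list(labels = as.character(unlist(s$labels %||% character())), prob = s$prob))
  part <- config$partition
  pf <- switch(part$rule,
    xx_vs_partner = partition_xx_vs_partner(unlist(part$x_labels), part$partner),
    two_compounds = partition_two_compounds(part$a, part$b),
    mono_vs_44 = partition_mono_vs_44(part$mono),
    stop("unknown partition rule: ", part$rule))
  cross_design(female, sperm, hs_pairs = unlist(config$hs_pairs),
               partition_fun = pf,
               unscored_ova = unlist(config$unscored_ova %||% character()),
               viability = v, label = config$label %||% "")
}
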