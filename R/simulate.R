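## Seeded Monte-Carlo forward simulator: oocyte configurations and progeny
## count tables with the statistical structure the estimators assume.

# evaluate expr under set.seed(seed) without disturbing the caller's stream
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation specification
#'
#' Bundles everything one simulated experiment needs. A given spec and seed
#' always reproduce the same counts (single global RNG stream per run); with
#' `seed = NULL` the simulator consumes the caller's RNG stream instead.
#'
#' @param design a [cross_design()].
#' @param params a [meiosis_params()] (defaults to the genotype's study
#'   conditions when the design matches a preset are *not* guessed -- pass
#'   explicitly).
#' @param n_oocytes number of oocytes scored by [simulate_oocytes()].
#' @param n_progeny_target number of scored surviving progeny accumulated by
#'   [simulate_cross()].
#' @param stage_mix probability a sampled oocyte is scored at prometaphase I
#'   (2-d mated prep) rather than metaphase I arrest (4-d virgin prep).
#' @param movement_prob probability a prometaphase oocyte has at least one
#'   chromosome out on the spindle (genotype-dependent; free parameter).
#' @param compound_out_frac probability the compound is among the chromosomes
#'   out, given any are out.
#' @param residual_out_prob probability a nominally metaphase-arrested oocyte
#'   is still in prometaphase (chromosomes not yet congressed).
#' @param other_config_prob probability of a non-heterologous malorientation
#'   at metaphase.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(design, params, n_oocytes = 0,
                            n_progeny_target = 0, stage_mix = 0.5,
                            movement_prob = 0.5, compound_out_frac = 0.5,
                            residual_out_prob = 0.05, other_config_prob = 0,
                            seed = 1L) {
  stopifnot(inherits(design, "cross_design"), inherits(params, "meiosis_params"),
            n_oocytes >= 0, n_progeny_target >= 0)
  for (p in c(stage_mix, movement_prob, compound_out_frac, residual_out_prob,
              other_config_prob))
    if (p < 0 || p > 1) stop("simulation probabilities must be in [0, 1]")
  structure(list(design = design, params = params, n_oocytes = n_oocytes,
                 n_progeny_target = n_progeny_target, stage_mix = stage_mix,
                 movement_prob = movement_prob,
                 compound_out_frac = compound_out_frac,
                 residual_out_prob = residual_out_prob,
                 other_config_prob = other_config_prob, seed = seed),
            class = "simulation_spec")
}

#' Simulate scored oocyte configurations
#'
#' Draws oocytes at the spec's stage mix. Metaphase-arrest oocytes draw their
#' orientation class from the same distribution that governs segregation
#' (heterologous biorientation with probability [hs_orientation_prob()]);
#' prometaphase oocytes additionally draw a movement indicator. Movement and
#' eventual orientation are drawn independently.
#'
#' @param s a [simulation_spec()] with `n_oocytes > 0`.
#' @return data frame in the oocyte count schema (one row per stage present):
#'   `stage, single_mass, one_plus_out, compound_out, hs_config,
#'   other_config`, with the seed recorded as an attribute.
#' @export
simulate_oocytes <- function(s) {
  stopifnot(inherits(s, "simulation_spec"))
  if (s$n_oocytes <= 0) stop("n_oocytes must be positive")
  p_hs <- hs_orientation_prob(s$design$female, s$params)
  if (p_hs + s$other_config_prob > 1)
    stop("hs and other malorientation probabilities exceed 1")
  with_sim_seed(s$seed, {
    n_pro <- stats::rbinom(1, s$n_oocytes, s$stage_mix)
    n_met <- s$n_oocytes - n_pro
    pro_out <- stats::rbinom(1, n_pro, s$movement_prob)
    pro_comp <- stats::rbinom(1, pro_out, s$compound_out_frac)
    met_out <- stats::rbinom(1, n_met, s$residual_out_prob)
    orient <- stats::rmultinom(1, n_met,
                               c(hs = p_hs, other = s$other_config_prob,
                                 normal = 1 - p_hs - s$other_config_prob))
    out <- data.frame(
      stage = c("prometaphase_2d", "metaphase_4d"),
      single_mass = c(n_pro - pro_out, n_met - met_out),
      one_plus_out = c(pro_out, met_out),
      compound_out = c(pro_comp, 0L),
      hs_config = c(0L, orient["hs", 1]),
      other_config = c(0L, orient["other", 1]),
      stringsAsFactors = FALSE)
    out <- out[c(n_pro, n_met) > 0, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "seed") <- s$seed
    out
  })
}

#' Simulate a segregation assay
#'
#' Repeatedly draws an ovum class from the exact gamete distribution, a sperm
#' class, a survival Bernoulli from the viability model, and the phenotype
#' class, accumulating until `n_progeny_target` surviving *scored* progeny
#' have been collected (flies are scored, not attempted zygotes). Survivors of
#' unscored classes are discarded. In exchange meioses the transmitted X is
#' recombinant with probability `p_recombinant`; recombinant survivors are
#' tallied as `other`/`recombinant` regardless of their segregation class.
#'
#' @param s a [simulation_spec()] with `n_progeny_target > 0`.
#' @return a [progeny_count_table()] with attributes `seed`, `n_attempted`
#'   (zygotes drawn) and `n_survivors` (before the scored filter).
#' @export
simulate_cross <- function(s) {
  stopifnot(inherits(s, "simulation_spec"))
  target <- s$n_progeny_target
  if (target <= 0) stop("n_progeny_target must be positive")
  design <- s$design
  dist <- gamete_distribution(design$female, s$params)
  ovum_keys <- names(dist$prob)
  sperm_keys <- names(design$sperm_classes)
  sperm_prob <- vapply(design$sperm_classes, `[[`, numeric(1), "prob")
  cls <- design$classes
  idx <- function(o, sp) match(paste(o, sp), paste(cls$ovum, cls$sperm))
  grid <- expand.grid(o = seq_along(ovum_keys), s = seq_along(sperm_keys))
  rowid <- matrix(idx(ovum_keys[grid$o], sperm_keys[grid$s]),
                  nrow = length(ovum_keys))
  if (anyNA(rowid))
    stop("simulation parameters produce ovum classes not covered by the design")
  surv <- matrix(cls$survival[rowid], nrow = length(ovum_keys))
  scored <- matrix(cls$scored[rowid], nrow = length(ovum_keys))
  part <- matrix(cls$partition[rowid], nrow = length(ovum_keys))
  f <- sum(outer(dist$prob, sperm_prob) * surv * scored)
  if (f <= 0) stop("no recoverable scored class under this design")

  counts <- c(normal = 0L, hs_exceptional = 0L, other = 0L,
              recombinant = 0L, paternal_ndj = 0L)
  n_attempted <- 0L; n_survivors <- 0L; got <- 0L
  p_rec <- dist$p_exchange_origin * s$params$p_recombinant

  with_sim_seed(s$seed, {
    while (got < target) {
      m <- min(2e6, as.integer(ceiling((target - got) / f * 1.25)) + 100L)
      oi <- sample.int(length(ovum_keys), m, replace = TRUE, prob = dist$prob)
      sj <- sample.int(length(sperm_keys), m, replace = TRUE, prob = sperm_prob)
      ij <- cbind(oi, sj)
      alive <- stats::runif(m) < surv[ij]
      n_attempted <- n_attempted + m
      n_survivors <- n_survivors + sum(alive)
      keep <- alive & scored[ij]
      if (!any(keep)) next
      oi <- oi[keep]; sj <- sj[keep]
      pt <- part[cbind(oi, sj)]
      rec <- stats::runif(length(oi)) < p_rec[oi]
      pt[rec] <- "recombinant"
      room <- target - got
      if (length(pt) > room) pt <- pt[seq_len(room)]
      tb <- table(factor(pt, levels = c("normal", "hs_exceptional", "other",
                                        "recombinant")))
      counts["normal"] <- counts["normal"] + tb[["normal"]]
      counts["hs_exceptional"] <- counts["hs_exceptional"] + tb[["hs_exceptional"]]
      counts["other"] <- counts["other"] + tb[["other"]] + tb[["recombinant"]]
      counts["recombinant"] <- counts["recombinant"] + tb[["recombinant"]]
      got <- got + length(pt)
    }
  })
  out <- progeny_count_table(counts[["normal"]], counts[["hs_exceptional"]],
                             counts[["other"]], counts[["recombinant"]], 0)
  attr(out, "seed") <- s$seed
  attr(out, "n_attempted") <- n_attempted
  attr(out, "n_survivors") <- n_survivors
  out
}

#' Closed-loop parameter recovery experiment
#'
#' For each true HS rate in `p_grid`, repeatedly simulates a cross, estimates
#' the corrected genetic HS rate, and records whether the 95 percent interval
#' covers the truth. The default design is an XXY female heterozygous for a
#' crossover-blocking balancer, where the secondary nondisjunction probability
#' *is* the HS rate and the correction factor is 2; for double-compound
#' designs the pair's co-orientation probability is set to `2 p - 1` so the
#' single-compound (HS) rate equals `p` (requires `p >= 0.5`).
#'
#' @param p_grid numeric vector of true HS rates in `[0, 1]` (may be empty).
#' @param n_replicates simulated crosses per grid point.
#' @param n_progeny scored progeny per simulated cross.
#' @param design a [cross_design()] with a single heterolog pair.
#' @param conf confidence level.
#' @param seed integer seed for the whole experiment (single RNG stream).
#' @return data frame with one row per replicate (`p_true, replicate,
#'   estimate_pct, ci_low, ci_high, covered`) and a per-grid-point summary
#'   (`p_true, mean_estimate_pct, bias_pp, coverage`) in the `"summary"`
#'   attribute.
#' @export
recovery_report <- function(p_grid, n_replicates = 100, n_progeny = 5000,
                            design = cross_preset("FM7_XXY"), conf = 0.95,
                            seed = 1L) {
  stopifnot(all(p_grid >= 0 & p_grid <= 1))
  if (length(design$hs_pairs) != 1L)
    stop("recovery_report needs a design with exactly one heterolog pair")
  pair <- design$hs_pairs
  units <- strsplit(pair, "|", fixed = TRUE)[[1]]
  xx_pair <- "XX" %in% units
  empty <- data.frame(p_true = numeric(), replicate = integer(),
                      estimate_pct = numeric(), ci_low = numeric(),
                      ci_high = numeric(), covered = logical())
  if (!length(p_grid)) {
    attr(empty, "summary") <- data.frame(p_true = numeric(),
                                         mean_estimate_pct = numeric(),
                                         bias_pp = numeric(),
                                         coverage = numeric())
    return(empty)
  }
  factor <- correction_factor(design)
  rows <- vector("list", length(p_grid) * n_replicates)
  k <- 0L
  with_sim_seed(seed, {
    for (p in p_grid) {
      pr <- if (xx_pair) p else {
        if (p < 0.5)
          stop("double-compound designs support HS rates >= 0.5 (rate = (1+q)/2)")
        2 * p - 1
      }
      params <- meiosis_params(
        p_nonexchange_X = 1,
        p_hs = stats::setNames(list(pr), pair))
      spec <- simulation_spec(design, params, n_progeny_target = n_progeny,
                              seed = NULL)
      for (r in seq_len(n_replicates)) {
        t <- simulate_cross(spec)
        est <- genetic_hs_rate(t, factor, decimals = 6, conf = conf)
        k <- k + 1L
        rows[[k]] <- data.frame(
          p_true = p, replicate = r, estimate_pct = 100 * est$numerator / est$denominator,
          ci_low = est$ci_low, ci_high = est$ci_high,
          covered = est$ci_low <= 100 * p && 100 * p <= est$ci_high)
      }
    }
  })
  out <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(out, out$p_true), function(d)
    data.frame(p_true = d$p_true[1],
               mean_estimate_pct = mean(d$estimate_pct),
               bias_pp = mean(d$estimate_pct) - 100 * d$p_true[1],
               coverage = mean(d$covered))))
  rownames(sm) <- NULL
  attr(out, "summary") <- sm
  out
}
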