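## Viability-corrected rate estimators and supporting statistics.

# round half away from zero at `digits` decimals (printed-table convention)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

#' Oocyte configuration counts
#'
#' Counts of fixed oocytes per cytological configuration class at one meiotic
#' stage. `single_mass` (all chromosomes congressed) and `one_plus_out` (at
#' least one chromosome out on the spindle) are mutually exclusive;
#' `compound_out` is the subset of `one_plus_out` where the compound itself
#' was out; `hs_config` is the subset of oocytes (either column) with a
#' heterologous biorientation; `other_config` counts other malorientations.
#'
#' @param stage `"prometaphase_2d"` (2-d mated females) or `"metaphase_4d"`
#'   (4-d aged virgins).
#' @param single_mass,one_plus_out,compound_out,hs_config,other_config
#'   nonnegative integer counts.
#' @return object of class `oocyte_config_counts`.
#' @export
oocyte_config_counts <- function(stage = c("metaphase_4d", "prometaphase_2d"),
                                 single_mass, one_plus_out = 0,
                                 compound_out = 0, hs_config = 0,
                                 other_config = 0) {
  stage <- match.arg(stage)
  counts <- c(single_mass = single_mass, one_plus_out = one_plus_out,
              compound_out = compound_out, hs_config = hs_config,
              other_config = other_config)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("oocyte counts must be nonnegative integers")
  if (compound_out > one_plus_out)
    stop("compound_out must be a subset of one_plus_out")
  if (hs_config > single_mass + one_plus_out)
    stop("hs_config must be a subset of the scored oocytes")
  structure(c(list(stage = stage), as.list(counts)),
            class = "oocyte_config_counts")
}

#' Progeny counts from a segregation assay
#'
#' @param normal count of progeny from regular segregation classes.
#' @param hs_exceptional count of surviving heterologous-segregation
#'   (or secondary nondisjunction) exceptional progeny, before correction.
#' @param other all remaining scored progeny.
#' @param recombinant subset of `other` carrying a maternal recombinant.
#' @param paternal_ndj subset of `other` arising from paternal nondisjunction.
#' @return object of class `progeny_count_table`.
#' @export
progeny_count_table <- function(normal, hs_exceptional = 0, other = 0,
                                recombinant = 0, paternal_ndj = 0) {
  counts <- c(normal = normal, hs_exceptional = hs_exceptional, other = other,
              recombinant = recombinant, paternal_ndj = paternal_ndj)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("progeny counts must be nonnegative integers")
  if (recombinant + paternal_ndj > other)
    stop("recombinant + paternal_ndj must be a subset of 'other'")
  storage.mode(counts) <- "integer"
  structure(as.list(counts), class = "progeny_count_table")
}

#' @export
print.progeny_count_table <- function(x, ...) {
  cat(sprintf(
    "<progeny_count_table: normal %d, HS-exceptional %d, other %d (recombinant %d, paternal NDJ %d)>\n",
    x$normal, x$hs_exceptional, x$other, x$recombinant, x$paternal_ndj))
  invisible(x)
}

#' @export
print.oocyte_config_counts <- function(x, ...) {
  cat(sprintf(
    "<oocyte_config_counts [%s]: single mass %d, 1+ out %d (compound out %d), HS %d, other %d>\n",
    x$stage, x$single_mass, x$one_plus_out, x$compound_out, x$hs_config,
    x$other_config))
  invisible(x)
}

#' Cytological configuration rates
#'
#' Percentages of scored oocytes per configuration class. The denominator for
#' every rate is `single_mass + one_plus_out` (the mutually exclusive scored
#' total); the subset columns are never added to it. Rates are rounded to the
#' nearest integer percent (half away from zero), matching how such counts
#' are reported.
#'
#' @param c an [oocyte_config_counts()].
#' @return named list with `pct_single_mass`, `pct_one_plus_out`,
#'   `pct_compound_out`, `pct_hs`, and the denominator `n_scored`.
#' @examples
#' cytological_rates(oocyte_config_counts("metaphase_4d", 112, 9, hs_config = 2))
#' @export
cytological_rates <- function(c) {
  stopifnot(inherits(c, "oocyte_config_counts"))
  n <- c$single_mass + c$one_plus_out
  if (n == 0) stop("empty sample: no scored oocytes")
  pct <- function(k) round_half_away(100 * k / n, 0)
  list(pct_single_mass = pct(c$single_mass),
       pct_one_plus_out = pct(c$one_plus_out),
       pct_compound_out = pct(c$compound_out),
       pct_hs = pct(c$hs_config),
       n_scored = n)
}

#' Viability correction factor for exceptional progeny counts
#'
#' Derives, from the cross design and its viability model, the multiplier that
#' puts surviving HS-exceptional progeny counts on the same recovery scale as
#' the scored reference classes. For each ovum class the expected recovery is
#' the sperm-class-weighted probability that the zygote survives the hard
#' lethality rules and is scored; exceptional minute classes count as
#' unrecoverable when `v_minute = 0`, whereas minutes inside the bulk normal
#' classes are scored along with everything else. The factor is the ratio of
#' mean reference recovery to mean exceptional recovery (weighted by the
#' classes' conditional frequencies): each halving of exceptional recovery
#' relative to the reference doubles the factor, giving 2 when half the
#' exceptional zygotes die of the wrong sperm genotype and 4 when one of the
#' two surviving exceptional classes is additionally unrecoverable. Crosses in
#' which every scored class suffers the same loss yield factor 1.
#'
#' @param design a [cross_design()].
#' @return the correction multiplier (numeric; 1, 2 and 4 for the modelled
#'   cross families).
#' @examples
#' correction_factor(cross_preset("FM7_C4"))  # 4: sperm lethality + minute loss
#' @export
correction_factor <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  cls <- design$classes
  recovery_by_ovum <- function(rows) {
    sp <- split(rows, rows$ovum)
    rec <- vapply(sp, function(d)
      sum(d$sperm_prob * d$hard_survival * d$scored), numeric(1))
    w <- vapply(sp, function(d) d$ovum_prob[1], numeric(1))
    sum(w * rec) / sum(w)
  }
  exc <- cls[cls$partition == "hs_exceptional", ]
  if (nrow(exc) == 0) stop("cross design has no exceptional classes")
  ref <- cls[cls$partition == "normal", ]
  if (nrow(ref) == 0) ref <- cls[cls$partition == "other", ]
  if (nrow(ref) == 0) stop("cross design has no reference classes")
  r_exc <- recovery_by_ovum(exc)
  if (r_exc <= 0)
    stop("no recoverable exceptional class under this viability model")
  recovery_by_ovum(ref) / r_exc
}

#' Corrected rate estimate
#'
#' Internal constructor for the rate + interval container returned by
#' [genetic_hs_rate()].
#' @noRd
rate_estimate <- function(point, numerator, denominator, ci, factor, decimals) {
  structure(list(point = point, numerator = numerator,
                 denominator = denominator,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 correction_applied = factor, decimals = decimals),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate: %s%% (95%% CI %.2f-%.2f), %g / %g, correction x%g>\n",
              format(x$point), x$ci_low, x$ci_high, x$numerator, x$denominator,
              x$correction_applied))
  invisible(x)
}

#' Viability-corrected heterologous segregation rate
#'
#' The genetic HS (or secondary nondisjunction) rate estimated from a progeny
#' count table: surviving exceptional progeny are multiplied by the viability
#' correction factor, and the denominator is the corrected total of scored
#' progeny attributable to the female's meioses -- normal progeny, the
#' corrected exceptional count, and other scored progeny excluding paternal
#' nondisjunction (maternal recombinants are included, uncorrected).
#'
#' The confidence interval is a Wilson score interval computed on the *raw*
#' scored proportion and transformed through the monotone correction map
#' `r = F e / (1 + (F - 1) e)`; applying Wilson directly to inflated counts
#' would understate the sampling variance of the corrected rate.
#'
#' @param t a [progeny_count_table()].
#' @param factor correction multiplier (from [correction_factor()]; >= 1).
#' @param decimals decimal places of the reported percentage (0 or 1 in the
#'   published tables).
#' @param conf confidence level for the Wilson interval.
#' @return a `rate_estimate` with the percentage, corrected counts and CI.
#' @examples
#' genetic_hs_rate(progeny_count_table(1232, 25), factor = 4)  # 7.5%
#' @export
genetic_hs_rate <- function(t, factor, decimals = 1, conf = 0.95) {
  stopifnot(inherits(t, "progeny_count_table"))
  if (factor < 1) stop("correction factor must be >= 1")
  num <- factor * t$hs_exceptional
  other_scored <- t$other - t$paternal_ndj
  den <- t$normal + num + other_scored
  if (den <= 0) stop("empty sample: corrected denominator is zero")
  point <- round_half_away(100 * num / den, decimals)
  # raw scored proportion, then the correction map
  n_raw <- t$normal + t$hs_exceptional + other_scored
  wi <- wilson_interval(t$hs_exceptional, n_raw, conf = conf) / 100
  transform <- function(e) 100 * factor * e / (1 + (factor - 1) * e)
  rate_estimate(point, num, den, transform(wi), factor, decimals)
}

#' Map distance from recombinant progeny
#'
#' Map distance in centimorgans between the scored markers:
#' `100 * recombinant / (normal + factor * hs_exceptional + recombinant)`,
#' rounded to one decimal. Recombinant counts receive no viability correction;
#' the exceptional class is corrected so the denominator approximates the
#' total number of scored meioses.
#'
#' @param t a [progeny_count_table()] with `recombinant <= other`.
#' @param factor correction multiplier applied to the exceptional class.
#' @return map distance in cM (one decimal).
#' @examples
#' t <- progeny_count_table(1426, 1371, other = 28, recombinant = 25,
#'                          paternal_ndj = 3)
#' map_distance(t, factor = 2)  # 0.6 cM
#' @export
map_distance <- function(t, factor = 1) {
  stopifnot(inherits(t, "progeny_count_table"))
  den <- t$normal + factor * t$hs_exceptional + t$recombinant
  if (den <= 0) stop("empty sample: map-distance denominator is zero")
  round_half_away(100 * t$recombinant / den, 1)
}

#' Wilson score interval for a proportion
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (> 0).
#' @param conf confidence level.
#' @return numeric vector `c(low, high)` in percent.
#' @examples
#' wilson_interval(2, 121)
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("empty sample: n must be > 0")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  100 * c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Compare a cytological rate with a corrected genetic rate
#'
#' Two-sided Fisher exact test on the 2x2 table of (rounded) corrected
#' counts, plus a Wilson-interval overlap flag. The published study asserts
#' concordance between biorientation rates at metaphase I arrest and
#' segregation rates inferred from progeny without a formal test; this
#' operationalizes the comparison for small exceptional counts.
#'
#' @param cyt `c(k, n)` cytological HS count and scored total.
#' @param gen `c(k, n)` corrected genetic numerator and denominator.
#' @param conf confidence level for the interval-overlap flag.
#' @return list with `p_value`, `rate_difference` (percentage points,
#'   genetic minus cytological), and `ci_overlap`.
#' @examples
#' compare_rates(c(2, 54), c(80, 2156))
#' @export
compare_rates <- function(cyt, gen, conf = 0.95) {
  if (cyt[2] <= 0 || gen[2] <= 0) stop("empty sample in rate comparison")
  k1 <- round(cyt[1]); n1 <- round(cyt[2])
  k2 <- round(gen[1]); n2 <- round(gen[2])
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  ci1 <- wilson_interval(k1, n1, conf)
  ci2 <- wilson_interval(k2, n2, conf)
  list(p_value = p,
       rate_difference = 100 * (k2 / n2 - k1 / n1),
       ci_overlap = ci1[1] <= ci2[2] && ci2[1] <= ci1[2])
}
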