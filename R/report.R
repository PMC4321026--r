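## Table-level estimation helpers shared by the CLI, the vignette and the
## reproduction scripts.

#' Corrected genetic rates for a progeny count table
#'
#' Applies [genetic_hs_rate()] to every row of a progeny table data frame.
#' The correction factor for each row is derived from its genotype's preset
#' cross design ([cross_preset()] + [correction_factor()]) unless `factor` is
#' given; the reporting precision comes from the table's `decimals` column
#' (default 1).
#'
#' @param progeny data frame in the progeny schema (see [load_counts()]),
#'   with a `genotype` column unless `factor` is supplied.
#' @param factor optional fixed correction multiplier overriding derivation.
#' @return data frame with genotype, correction factor, corrected counts,
#'   rate (at the row's reporting precision), Wilson CI, and map distance in
#'   cM where recombinants were scored (NA otherwise).
#' @examples
#' estimate_genetic_rates(load_table1()$progeny)
#' @export
estimate_genetic_rates <- function(progeny, factor = NULL) {
  rows <- lapply(seq_len(nrow(progeny)), function(i) {
    row <- progeny[i, , drop = FALSE]
    t <- as_progeny_count_table(row)
    f <- factor
    if (is.null(f)) {
      if (is.null(row$genotype))
        stop("progeny table has no genotype column; supply 'factor'")
      f <- correction_factor(cross_preset(row$genotype))
    }
    dec <- if (!is.null(row$decimals)) row$decimals else 1
    est <- genetic_hs_rate(t, f, decimals = dec)
    data.frame(
      genotype = if (!is.null(row$genotype)) row$genotype else NA_character_,
      factor = f, numerator = est$numerator, denominator = est$denominator,
      hs_rate_pct = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
      map_cM = if (t$recombinant > 0) map_distance(t, f) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cytological rates for an oocyte count table
#'
#' Applies [cytological_rates()] to every row of an oocyte table data frame.
#'
#' @param cytology data frame in the oocyte schema.
#' @return data frame with genotype, stage, scored total and the four
#'   integer percentages.
#' @examples
#' estimate_cytological_rates(load_table2()$cytology)
#' @export
estimate_cytological_rates <- function(cytology) {
  rows <- lapply(seq_len(nrow(cytology)), function(i) {
    row <- cytology[i, , drop = FALSE]
    r <- cytological_rates(as_oocyte_config_counts(row))
    data.frame(
      genotype = if (!is.null(row$genotype)) row$genotype else NA_character_,
      stage = row$stage, n_scored = r$n_scored,
      pct_single_mass = r$pct_single_mass,
      pct_one_plus_out = r$pct_one_plus_out,
      pct_compound_out = r$pct_compound_out,
      pct_hs = r$pct_hs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cytology-versus-genetics concordance for a preset genotype
#'
#' Pairs a genotype's metaphase biorientation counts with its corrected
#' genetic counts (both from the packaged tables) and runs [compare_rates()].
#' When the cytology table records an `hs_recoverable` subset (biorientation
#' classes whose segregation products are viable and attributable in the
#' progeny), that subset is compared; a malorientation that is lethal in the
#' progeny can be seen down the microscope but never in a count table.
#'
#' @param genotype a preset name present in the packaged tables (both count
#'   types).
#' @return the [compare_rates()] result plus the two (k, n) pairs.
#' @export
concordance_test <- function(genotype) {
  t1 <- load_table1(); t2 <- load_table2()
  cyt <- rbind(t1$cytology, t2$cytology)
  gen <- rbind(t1$progeny[names(t2$progeny)], t2$progeny)
  cy <- cyt[cyt$genotype == genotype & cyt$stage == "metaphase_4d", , drop = FALSE]
  ge <- gen[gen$genotype == genotype, , drop = FALSE]
  if (nrow(cy) != 1L || nrow(ge) != 1L)
    stop("genotype not present in both packaged tables: ", genotype)
  r <- cytological_rates(as_oocyte_config_counts(cy))
  est <- estimate_genetic_rates(ge)
  k_cyt <- if (!is.null(cy$hs_recoverable)) cy$hs_recoverable else cy$hs_config
  cmp <- compare_rates(c(k_cyt, r$n_scored),
                       c(est$numerator, est$denominator))
  c(cmp, list(cytological = c(k = k_cyt, n = r$n_scored),
              genetic = c(k = est$numerator, n = est$denominator)))
}
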