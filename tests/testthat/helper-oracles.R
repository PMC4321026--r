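# Independent oracles used across the suite.

# Hand-enumerated gamete class distributions for each supported genotype
# family, written as explicit closed forms over the pole-assignment events
# (engagement -> side choice; otherwise per-unit independent segregation).
# Kept deliberately separate from the package's recursive implementation.
expected_gamete_dist <- function(preset, pe = 0, p = 0, q = 0, h = 0) {
  norm <- function(x) x[order(names(x))]
  key <- function(...) paste(sort(c(...)), collapse = "+")
  out <- switch(preset,
    C1_mono = c(
      stats::setNames(h / 2, key("C1")),
      stats::setNames(h / 2, key("4", "4")),
      stats::setNames((1 - h) / 2, key("C1", "4")),
      stats::setNames((1 - h) / 2, key("4"))),
    C2EN_mono = c(
      stats::setNames(h / 2, key("C2EN", "X")),
      stats::setNames(h / 2, key("4", "4", "X")),
      stats::setNames((1 - h) / 2, key("C2EN", "4", "X")),
      stats::setNames((1 - h) / 2, key("4", "X"))),
    C4_mono = c(
      stats::setNames(pe * h / 2, key("X.ywf", "X.ywf")),
      stats::setNames(pe * h / 2, key("C4")),
      stats::setNames((1 - pe * h) / 2, key("X.ywf", "C4")),
      stats::setNames((1 - pe * h) / 2, key("X.ywf"))),
    In1_C4 = c(
      stats::setNames(pe * h / 2, key("In1", "X.ywf")),
      stats::setNames(pe * h / 2, key("C4")),
      stats::setNames((1 - pe * h) / 4, key("X.ywf", "C4")),
      stats::setNames((1 - pe * h) / 4, key("X.ywf")),
      stats::setNames((1 - pe * h) / 4, key("In1", "C4")),
      stats::setNames((1 - pe * h) / 4, key("In1"))),
    FM7_C4 = c(  # balancer: nonexchange with certainty, pe ignored
      stats::setNames(h / 2, key("FM7", "X.ywf")),
      stats::setNames(h / 2, key("C4")),
      stats::setNames((1 - h) / 4, key("X.ywf", "C4")),
      stats::setNames((1 - h) / 4, key("X.ywf")),
      stats::setNames((1 - h) / 4, key("FM7", "C4")),
      stats::setNames((1 - h) / 4, key("FM7"))),
    XXY_yw = c(
      stats::setNames(pe * p / 2, key("X.yw", "X.yw", "4")),
      stats::setNames(pe * p / 2, key("yY", "4")),
      stats::setNames((1 - pe * p) / 2, key("X.yw", "4")),
      stats::setNames((1 - pe * p) / 2, key("X.yw", "yY", "4"))),
    FM7_XXY = c(
      stats::setNames(p / 2, key("FM7", "X.yw", "4")),
      stats::setNames(p / 2, key("yY", "4")),
      stats::setNames((1 - p) / 4, key("FM7", "4")),
      stats::setNames((1 - p) / 4, key("X.yw", "4")),
      stats::setNames((1 - p) / 4, key("FM7", "yY", "4")),
      stats::setNames((1 - p) / 4, key("X.yw", "yY", "4"))),
    In1_XXY = c(
      stats::setNames(pe * p / 2, key("In1", "X.ywf", "4")),
      stats::setNames(pe * p / 2, key("Y", "4")),
      stats::setNames((1 - pe * p) / 4, key("In1", "4")),
      stats::setNames((1 - pe * p) / 4, key("X.ywf", "4")),
      stats::setNames((1 - pe * p) / 4, key("In1", "Y", "4")),
      stats::setNames((1 - pe * p) / 4, key("X.ywf", "Y", "4"))),
    C1C4 = c(
      stats::setNames(q / 2 + (1 - q) / 4, key("C1")),
      stats::setNames(q / 2 + (1 - q) / 4, key("C4")),
      stats::setNames((1 - q) / 4, key("C1", "C4")),
      stats::setNames((1 - q) / 4, "none")),
    C2L_C2R = c(
      stats::setNames(q / 2 + (1 - q) / 4, key("C2L", "X", "4")),
      stats::setNames(q / 2 + (1 - q) / 4, key("C2R", "X", "4")),
      stats::setNames((1 - q) / 4, key("C2L", "C2R", "X", "4")),
      stats::setNames((1 - q) / 4, key("X", "4"))),
    stop("no oracle for preset ", preset)
  )
  norm(out[out > 0])
}

# parameter objects matching the oracle's (pe, p, q, h) for a preset
oracle_params <- function(preset, pe = 0, p = 0, q = 0, h = 0) {
  switch(preset,
    C1_mono   = meiosis_params(p_hs = list("44|C1" = h)),
    C2EN_mono = meiosis_params(p_nonexchange_X = pe, p_hs = list("44|C2EN" = h)),
    C4_mono   = meiosis_params(p_nonexchange_X = pe, p_hs = list("C4|XX" = h)),
    In1_C4    = meiosis_params(p_nonexchange_X = pe, p_hs = list("C4|XX" = h)),
    FM7_C4    = meiosis_params(p_nonexchange_X = pe, p_hs = list("C4|XX" = h)),
    XXY_yw    = meiosis_params(p_nonexchange_X = pe, p_secondary_ndj = p),
    FM7_XXY   = meiosis_params(p_nonexchange_X = pe, p_secondary_ndj = p),
    In1_XXY   = meiosis_params(p_nonexchange_X = pe, p_secondary_ndj = p),
    C1C4      = meiosis_params(p_hs = list("C1|C4" = q)),
    C2L_C2R   = meiosis_params(p_hs = list("C2L|C2R" = q)),
    stop("no oracle params for preset ", preset)
  )
}

dist_as_vector <- function(d) d$prob[order(names(d$prob))]

# exhaustive hypergeometric tail sum for a two-sided Fisher exact test
fisher_oracle_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  xs <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(xs, n1, n2, m)
  obs <- stats::dhyper(k1, n1, n2, m)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# multiset complement of an ovum class within the maternal copy set
complement_key <- function(all_labels, class_labels) {
  rest <- all_labels
  for (lb in class_labels) {
    i <- match(lb, rest)
    rest <- rest[-i]
  }
  if (!length(rest)) "none" else paste(sort(rest), collapse = "+")
}

maternal_labels <- function(k) {
  sort(vapply(k$copies, `[[`, character(1), "label"))
}
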