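test_that("meiosis parameters are validated", {
  expect_error(meiosis_params(p_nonexchange_X = 1.2), "probability")
  expect_error(meiosis_params(p_secondary_ndj = -0.1), "probability")
  expect_error(meiosis_params(p_monovalent_recovery = 0.6), "exactly 0.5")
  expect_error(meiosis_params(p_hs = list(0.5)), "named")
  p <- meiosis_params(p_secondary_ndj = 0.3, p_hs = list("Y|XX" = 0.3))
  expect_identical(names(p$p_hs), "XX|Y")  # keys are unordered
})

test_that("analytic distribution matches the hand-enumerated oracle for every family", {
  cases <- list(
    list(preset = "C1_mono", pe = 0, p = 0, q = 0, h = 0.45),
    list(preset = "C2EN_mono", pe = 0.3, p = 0, q = 0, h = 0.25),
    list(preset = "C4_mono", pe = 0.3, p = 0, q = 0, h = 0.7),
    list(preset = "In1_C4", pe = 0.9, p = 0, q = 0, h = 0.15),
    list(preset = "FM7_C4", pe = 1, p = 0, q = 0, h = 0.6),
    list(preset = "XXY_yw", pe = 0.25, p = 0.8, q = 0, h = 0),
    list(preset = "FM7_XXY", pe = 1, p = 0.613, q = 0, h = 0),
    list(preset = "In1_XXY", pe = 0.95, p = 0.688, q = 0, h = 0),
    list(preset = "C1C4", pe = 0, p = 0, q = 0.942, h = 0),
    list(preset = "C2L_C2R", pe = 0, p = 0, q = 0.98, h = 0))
  for (cs in cases) {
    k <- karyotype_preset(cs$preset)
    d <- gamete_distribution(k, oracle_params(cs$preset, cs$pe, cs$p, cs$q, cs$h))
    got <- dist_as_vector(d)
    want <- expected_gamete_dist(cs$preset, cs$pe, cs$p, cs$q, cs$h)
    expect_identical(names(got), names(want), info = cs$preset)
    expect_equal(unname(got), unname(want), tolerance = 1e-14, info = cs$preset)
  }
})

test_that("zero co-orientation reduces to independent segregation", {
  # two monovalent heterologs at q = 0: the independence null, exactly
  d <- gamete_distribution(karyotype_preset("C1C4"),
                           meiosis_params(p_hs = list("C1|C4" = 0)))
  expect_identical(sort(names(d$prob)), c("C1", "C1+C4", "C4", "none"))
  expect_identical(unname(d$prob[order(names(d$prob))]), rep(0.25, 4))
  # XXY with secondary nondisjunction switched off: X<=>X with Y at random
  d <- gamete_distribution(karyotype_preset("XXY_yw"),
                           meiosis_params(p_nonexchange_X = 1,
                                          p_secondary_ndj = 0))
  want <- expected_gamete_dist("XXY_yw", pe = 1, p = 0)
  expect_equal(unname(dist_as_vector(d)), unname(want), tolerance = 1e-14)
})

test_that("certain secondary nondisjunction splits ova into XX and Y halves", {
  d <- gamete_distribution(karyotype_preset("XXY_yw"),
                           meiosis_params(p_nonexchange_X = 1,
                                          p_secondary_ndj = 1))
  expect_equal(unname(d$prob["4+X.yw+X.yw"]), 0.5, tolerance = 1e-15)
  expect_equal(unname(d$prob["4+yY"]), 0.5, tolerance = 1e-15)
})

test_that("probabilities normalize and complement classes have equal mass", {
  grid <- expand.grid(pe = c(0, 0.3, 1), pq = c(0, 0.5, 0.971))
  for (preset in list_presets()) {
    k <- karyotype_preset(preset)
    all_labels <- maternal_labels(k)
    for (i in seq_len(nrow(grid))) {
      pq <- grid$pq[i]
      params <- oracle_params(preset, pe = grid$pe[i], p = pq, q = pq, h = pq)
      d <- gamete_distribution(k, params)
      expect_lt(abs(sum(d$prob) - 1), 1e-12)
      # dose conservation: ovum class and its complementary pole class
      # partition the maternal centromeres and are equally likely
      for (key in names(d$prob)) {
        comp <- complement_key(all_labels, d$classes[[key]])
        expect_equal(unname(d$prob[key]), unname(d$prob[comp]),
                     tolerance = 1e-12,
                     info = sprintf("%s: %s vs %s", preset, key, comp))
      }
      # every class content is a sub-multiset of the maternal karyotype
      for (key in names(d$classes)) {
        tb <- table(d$classes[[key]])
        full <- table(factor(all_labels, levels = names(tb)))
        expect_true(all(tb <= full), info = paste(preset, key))
      }
    }
  }
})

test_that("heterologous pair probabilities cannot exceed one combined", {
  k <- karyotype_preset("C2EN_mono")
  expect_error(
    gamete_distribution(k, meiosis_params(p_hs = list("44|C2EN" = 0.7,
                                                      "C2EN|XX" = 0.7),
                                          p_nonexchange_X = 1)),
    "more than 1")
})

test_that("biorientation probability combines engagement and residual chance", {
  # two monovalents: q + (1 - q)/2
  k <- karyotype_preset("C1C4")
  expect_equal(hs_orientation_prob(k, meiosis_params(p_hs = list("C1|C4" = 0.942))),
               0.971, tolerance = 1e-12)
  expect_equal(hs_orientation_prob(k, meiosis_params(p_hs = list("C1|C4" = 0))),
               0.5, tolerance = 1e-12)
  # XX vs partner: engagement only, scaled by the nonexchange fraction
  k <- karyotype_preset("XXY_yw")
  expect_equal(
    hs_orientation_prob(k, meiosis_params(p_nonexchange_X = 0.075,
                                          p_secondary_ndj = 0.5)),
    0.0375, tolerance = 1e-12)
  # monovalent vs the 4 pair: engagement only
  k <- karyotype_preset("C1_mono")
  expect_equal(hs_orientation_prob(k, meiosis_params(p_hs = list("44|C1" = 0.02))),
               0.02, tolerance = 1e-12)
})
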