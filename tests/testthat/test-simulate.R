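xxy_spec <- function(p_sndj, n = 2000, seed = 11, ...) {
  simulation_spec(cross_preset("FM7_XXY"),
                  meiosis_params(p_nonexchange_X = 1,
                                 p_secondary_ndj = p_sndj),
                  seed = seed, ...)
}

test_that("identical seed and spec reproduce identical counts", {
  sp <- xxy_spec(0.65, n_progeny_target = 1500, n_oocytes = 800)
  t1 <- simulate_cross(sp); t2 <- simulate_cross(sp)
  expect_identical(unclass(t1)[], unclass(t2)[])
  o1 <- simulate_oocytes(sp); o2 <- simulate_oocytes(sp)
  expect_identical(o1, o2)
  sp2 <- xxy_spec(0.65, n_progeny_target = 1500, n_oocytes = 800, seed = 12)
  expect_false(identical(unclass(simulate_cross(sp2))[], unclass(t1)[]))
})

test_that("simulated oocyte configurations track the biorientation probability", {
  sp <- xxy_spec(0.65, n_oocytes = 5000, stage_mix = 0)
  oc <- simulate_oocytes(sp)
  met <- oc[oc$stage == "metaphase_4d", ]
  n <- met$single_mass + met$one_plus_out
  se <- sqrt(0.65 * 0.35 / n)
  expect_lt(abs(met$hs_config / n - 0.65), 3 * se)
  # exchange certain + no secondary nondisjunction: no HS configurations
  sp0 <- simulation_spec(cross_preset("XXY_yw"),
                         meiosis_params(p_nonexchange_X = 0,
                                        p_secondary_ndj = 0.9),
                         n_oocytes = 2000, stage_mix = 0, seed = 5)
  oc0 <- simulate_oocytes(sp0)
  expect_identical(oc0$hs_config[oc0$stage == "metaphase_4d"], 0L)
})

test_that("certain secondary nondisjunction yields only exceptional progeny", {
  t <- simulate_cross(xxy_spec(1, n_progeny_target = 400))
  expect_identical(t$normal, 0L)
  expect_identical(t$hs_exceptional, 400L)
})

test_that("surviving class composition matches the viability-filtered expectation", {
  # independence (q = 0) for the double-compound female: every scored class
  # recovers at the same rate, so scored fractions equal the gamete fractions
  des <- cross_preset("C1C4")
  sp <- simulation_spec(des, meiosis_params(p_hs = list("C1|C4" = 0)),
                        n_progeny_target = 4000, seed = 21)
  t <- simulate_cross(sp)
  n <- t$normal + t$hs_exceptional + t$other
  phat <- t$hs_exceptional / n            # single-compound (HS) classes
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(phat - 0.5), 3 * se)
  expect_identical(t$normal, 0L)          # no homologous pattern exists
  # analytic check of the scored-survivor fraction bookkeeping
  dist <- gamete_distribution(des$female, sp$params)
  cls <- des$classes
  sperm_p <- vapply(des$sperm_classes, `[[`, numeric(1), "prob")
  f <- sum(vapply(seq_len(nrow(cls)), function(i)
    unname(dist$prob[cls$ovum[i]]) * cls$sperm_prob[i] * cls$survival[i],
    numeric(1)))
  frac <- attr(t, "n_survivors") / attr(t, "n_attempted")
  se_f <- sqrt(f * (1 - f) / attr(t, "n_attempted"))
  expect_lt(abs(frac - f), 3 * se_f)
})

test_that("designs with no recoverable scored class fail loudly", {
  lethal <- viability_model(rules = list(
    list(name = "all_dead", test = function(dose, tracked) TRUE, p = 0)))
  des <- cross_preset("XXY_yw", viability = lethal)
  sp <- simulation_spec(des, meiosis_params(p_secondary_ndj = 0.5),
                        n_progeny_target = 10, seed = 2)
  expect_error(simulate_cross(sp), "no recoverable scored class")
})

test_that("corrected estimates are asymptotically unbiased for the true rate", {
  p <- 0.65
  est_at <- function(n, seed) {
    sp <- xxy_spec(p, n_progeny_target = n, seed = seed)
    e <- genetic_hs_rate(simulate_cross(sp), 2, decimals = 6)
    100 * e$numerator / e$denominator
  }
  err500 <- abs(vapply(1:40, function(s) est_at(500, s), numeric(1)) - 100 * p)
  err5000 <- abs(vapply(1:40, function(s) est_at(5000, s + 100), numeric(1)) - 100 * p)
  expect_lt(mean(err5000), mean(err500))   # error shrinks with sample size
  expect_lt(abs(mean(err5000)), 2)         # and is already small at n = 5000
})

test_that("recovery report covers the truth and handles an empty grid", {
  rep <- recovery_report(c(0.3, 0.8), n_replicates = 40, n_progeny = 1500,
                         seed = 9)
  expect_identical(nrow(rep), 80L)
  sm <- attr(rep, "summary")
  expect_identical(nrow(sm), 2L)
  expect_true(all(abs(sm$bias_pp) < 2))
  expect_true(all(sm$coverage > 0.8))      # loose sanity bound at 40 reps
  empty <- recovery_report(numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(attr(empty, "summary")), 0L)
})
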