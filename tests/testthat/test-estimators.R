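test_that("count table constructors validate their invariants", {
  expect_error(oocyte_config_counts("metaphase_4d", -1), "nonnegative")
  expect_error(oocyte_config_counts("metaphase_4d", 10, 5, compound_out = 6),
               "subset")
  expect_error(oocyte_config_counts("metaphase_4d", 10, 0, hs_config = 11),
               "subset")
  expect_error(progeny_count_table(10, other = 2, recombinant = 3), "subset")
  expect_error(progeny_count_table(-1), "nonnegative")
})

test_that("cytological rates use the scored-oocyte denominator and integer rounding", {
  r <- cytological_rates(oocyte_config_counts("metaphase_4d", 112, 9,
                                              hs_config = 2))
  expect_identical(r$pct_single_mass, 93)
  expect_identical(r$pct_hs, 2)
  r <- cytological_rates(oocyte_config_counts("prometaphase_2d", 32, 40,
                                              compound_out = 23))
  expect_identical(r$pct_one_plus_out, 56)
  expect_identical(r$pct_compound_out, 32)
  r <- cytological_rates(oocyte_config_counts("metaphase_4d", 250))
  expect_identical(r$pct_single_mass, 100)
  expect_identical(r$pct_hs, 0)
  expect_error(cytological_rates(oocyte_config_counts("metaphase_4d", 0)),
               "empty sample")
})

test_that("corrected genetic HS rates match the doubling/quadrupling arithmetic", {
  expect_identical(genetic_hs_rate(progeny_count_table(1232, 25), 4)$point, 7.5)
  expect_identical(genetic_hs_rate(progeny_count_table(2076, 40), 2)$point, 3.7)
  expect_identical(genetic_hs_rate(progeny_count_table(626, 9), 4)$point, 5.4)
  expect_identical(genetic_hs_rate(progeny_count_table(5000, 0), 4)$point, 0)
  expect_identical(genetic_hs_rate(progeny_count_table(182, 1), 4,
                                   decimals = 0)$point, 2)
  # paternal nondisjunction progeny leave the denominator; recombinants stay
  t <- progeny_count_table(1426, 1371, other = 28, recombinant = 25,
                           paternal_ndj = 3)
  est <- genetic_hs_rate(t, 2)
  expect_identical(est$point, 65.4)
  expect_identical(est$denominator, 1426 + 2 * 1371 + 25)
  expect_error(genetic_hs_rate(progeny_count_table(0, 0), 2), "empty sample")
  expect_error(genetic_hs_rate(progeny_count_table(10, 1), 0.5), ">= 1")
})

test_that("factor one equals the raw proportion and the estimate is monotone", {
  t <- progeny_count_table(900, 100)
  est <- genetic_hs_rate(t, 1, decimals = 6)
  expect_equal(est$point, 10, tolerance = 1e-9)
  # strictly increasing in the exceptional count, all else fixed
  rates <- vapply(c(0, 5, 25, 100, 400), function(k)
    genetic_hs_rate(progeny_count_table(1000, k), 2, decimals = 8)$point,
    numeric(1))
  expect_true(all(diff(rates) > 0))
  # interval always brackets the point and stays inside [0, 100]
  for (k in c(0, 3, 50)) {
    e <- genetic_hs_rate(progeny_count_table(200, k), 4)
    expect_true(e$ci_low >= 0 && e$ci_high <= 100)
    expect_true(e$ci_low <= 100 * e$numerator / e$denominator + 1e-9)
    expect_true(e$ci_high >= 100 * e$numerator / e$denominator - 1e-9)
  }
})

test_that("map distance divides recombinants by the corrected total", {
  t <- progeny_count_table(1426, 1371, other = 28, recombinant = 25,
                           paternal_ndj = 3)
  expect_identical(map_distance(t, 2), 0.6)
  expect_identical(map_distance(progeny_count_table(1000, 50), 2), 0)
  expect_error(map_distance(progeny_count_table(0, 0)), "empty sample")
})

test_that("the Wilson interval matches an independent implementation", {
  cases <- rbind(c(2, 121), c(0, 100), c(50, 100), c(40, 2156), c(999, 1000))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, 1]; n <- cases[i, 2]
    got <- wilson_interval(k, n, 0.95)
    want <- 100 * stats::prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-9)
  }
  expect_identical(unname(wilson_interval(0, 100)[1]), 0)
  ci <- wilson_interval(50, 100)
  expect_equal(unname(ci[1] + ci[2]), 100, tolerance = 1e-9)  # symmetry about 50
  expect_error(wilson_interval(1, 0), "empty sample")
  expect_error(wilson_interval(5, 4), "0 <= k <= n")
})

test_that("rate comparison reproduces the exact hypergeometric tail sum", {
  cases <- list(c(2, 54, 80, 2156), c(0, 100, 50, 100), c(5, 80, 36, 663))
  for (cs in cases) {
    got <- compare_rates(c(cs[1], cs[2]), c(cs[3], cs[4]))
    want <- fisher_oracle_p(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$p_value, want, tolerance = 1e-9)
  }
  expect_lt(compare_rates(c(0, 100), c(50, 100))$p_value, 1e-6)
  expect_equal(compare_rates(c(10, 100), c(10, 100))$p_value, 1, tolerance = 1e-12)
  expect_identical(compare_rates(c(10, 100), c(10, 100))$rate_difference, 0)
})
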