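test_that("fertilization adds element doses and keeps copy identities", {
  z <- fertilize(c("X.yw", "X.yw"), "Yp")
  expect_identical(unname(z$dose[c("X", "Y")]), c(2L, 1L))
  expect_identical(z$sex, "female")
  # empty-4 ovum plus a normal-4 sperm
  z <- fertilize(character(), "4p")
  expect_identical(unname(z$dose["4"]), 1L)
  # compound 2L ovum plus a whole normal chromosome 2
  two <- chromosome_copy("2n", c(`2L` = 1, `2R` = 1))
  z <- fertilize("C2L", "2n", copies = c(copy_catalog(), list(two)))
  expect_identical(unname(z$dose[c("2L", "2R")]), c(3L, 1L))
  expect_error(fertilize("nosuch", "Yp"), "unknown chromosome copy label")
})

test_that("survival applies first-match viability rules deterministically", {
  v <- viability_model()
  # triplo-X from an XX ovum and an X sperm dies
  expect_identical(survival(fertilize(c("X.yw", "X.yw"), "Xp"), v), 0)
  # haplo-4 gets v_minute
  z4 <- fertilize(c("X.ywf"), c("Xp", "4p"), tracked = c("X", "Y", "4"))
  expect_identical(survival(z4, v), 0)
  expect_identical(survival(z4, viability_model(v_minute = 0.3)), 0.3)
  # balanced zygotes survive
  expect_identical(survival(fertilize(c("X.yw", "4"), c("Yp", "4p")), v), 1)
  # triplo-4 viable, XYY male viable, YY-without-X dead
  expect_identical(survival(fertilize(c("X.ywf", "C4"), c("Xp", "4p")), v), 1)
  expect_identical(survival(fertilize(c("X.yw", "yY", "4"), c("Yp", "4p")), v), 1)
  expect_identical(survival(fertilize(c("yY", "4"), c("Yp", "4p")), v), 0)
})

test_that("survival is order-independent for non-overlapping rules", {
  rules <- list(
    list(name = "a", test = function(dose, tracked) dose["X"] >= 3L, p = 0),
    list(name = "b", test = function(dose, tracked) dose["4"] == 1L, p = 0.25),
    list(name = "c", test = function(dose, tracked) dose["Y"] >= 2L, p = 0.5))
  zygotes <- list(
    fertilize(c("X.yw", "X.yw"), "Xp"),
    fertilize("X.ywf", c("Xp", "4p"), tracked = c("X", "4")),
    fertilize(c("X.yw", "yY"), "Yp"),
    fertilize("X.yw", "Yp"))
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    v <- viability_model(rules = rules[perm])
    got <- vapply(zygotes, survival, numeric(1), v = v)
    expect_identical(got, c(0, 0.25, 0.5, 1))
  }
})

test_that("phenotype classes carry the scoring partition", {
  des <- cross_preset("XXY_yw")
  z <- fertilize(c("X.yw", "X.yw", "4"), c("Yp", "4p"))
  pc <- phenotype_class(z, des)
  expect_identical(attr(pc, "partition"), "hs_exceptional")
  z <- fertilize(c("X.yw", "4"), c("Yp", "4p"))
  expect_identical(attr(phenotype_class(z, des), "partition"), "normal")
  z <- fertilize(c("yY", "4"), c("Xp", "4p"))
  expect_identical(attr(phenotype_class(z, des), "partition"), "hs_exceptional")
  # inviable and uncovered zygotes are rejected explicitly
  expect_error(phenotype_class(fertilize(c("X.yw", "X.yw", "4"),
                                         c("Xp", "4p")), des),
               "survival > 0")
  expect_error(phenotype_class(fertilize("C1", "Yp"), des), "not covered")
})

test_that("correction factors are derived from the viability model, not hard-coded", {
  # sperm-genotype lethality halves exceptional recovery: x2
  expect_equal(correction_factor(cross_preset("XXY_yw")), 2, tolerance = 1e-12)
  expect_equal(correction_factor(cross_preset("In1_XXY")), 2, tolerance = 1e-12)
  # plus an unrecoverable minute exceptional class: x4
  expect_equal(correction_factor(cross_preset("FM7_C4")), 4, tolerance = 1e-12)
  expect_equal(correction_factor(cross_preset("In1_C4")), 4, tolerance = 1e-12)
  expect_equal(correction_factor(cross_preset("C4_mono")), 4, tolerance = 1e-12)
  expect_equal(correction_factor(cross_preset("C1_mono")), 4, tolerance = 1e-12)
  # double-compound crosses: every scored class suffers the same loss: x1
  expect_equal(correction_factor(cross_preset("C1C4")), 1, tolerance = 1e-12)
  expect_equal(correction_factor(cross_preset("C2L_C2R")), 1, tolerance = 1e-12)
})

test_that("toggling viability assumptions moves the correction factor", {
  # recoverable minutes drop the quadrupling back to the sperm-lethality x2
  expect_equal(correction_factor(
    cross_preset("FM7_C4", viability = viability_model(v_minute = 1))), 2,
    tolerance = 1e-12)
  # removing sex-chromosome lethality removes the sperm-genotype halving
  rules <- getFromNamespace("default_viability_rules", "hetseg")()
  no_sex_lethality <- Filter(function(r)
    !r$name %in% c("nullo_X", "triplo_X", "YY_without_X"), rules)
  v <- viability_model(rules = no_sex_lethality)
  expect_equal(correction_factor(cross_preset("XXY_yw", viability = v)), 1,
               tolerance = 1e-12)
})

test_that("cross designs load from JSON configuration", {
  cfg <- list(preset = "XXY_yw")
  des <- cross_design_from_config(cfg)
  expect_equal(correction_factor(des), 2, tolerance = 1e-12)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    label = "compound pair",
    female = list(preset = "C1C4"),
    sperm_classes = list(
      list(labels = list("C1YSp", "C4p"), prob = 0.25),
      list(labels = list("C1YSp"), prob = 0.25),
      list(labels = list("C4p"), prob = 0.25),
      list(labels = list(), prob = 0.25)),
    hs_pairs = list("C1|C4"),
    partition = list(rule = "two_compounds", a = "C1", b = "C4")),
    path, auto_unbox = TRUE)
  des <- cross_design_from_config(path)
  expect_equal(correction_factor(des), 1, tolerance = 1e-12)
})
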