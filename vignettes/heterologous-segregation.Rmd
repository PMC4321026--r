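---
title: "Modelling heterologous segregation and secondary nondisjunction in fly female meiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heterologous segregation and secondary nondisjunction in fly female meiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetseg)
```

## The problem

In *Drosophila melanogaster* females, meiosis I normally halves the genome by
segregating crossover-locked homologs. Some karyotypes cannot do this
everywhere: a compound chromosome (one DNA molecule carrying the euploid
complement of two chromosomes, e.g. an attached-X `C(1)RM` or attached-4
`C(4)RM`) has no homolog at all, and an XXY female has a Y with two potential
X partners. Such chromosomes nevertheless segregate nonrandomly:

* **Heterologous segregation (HS)** — two non-homologous chromosomes (two
  compounds, or a compound against the free 4 pair) co-orient and move to
  opposite poles far more often than chance.
* **Secondary nondisjunction** — in XXY females whose X chromosomes failed to
  cross over, the two Xs often segregate away from the Y together
  (the `XX <=> Y` pattern).

Measuring these rates from progeny counts is confounded by viability: many
segregation products die of aneuploidy or of receiving the wrong sperm
genotype, so the surviving exceptional classes must be scaled back up.
`hetseg` implements (i) an exact forward model of gamete formation for these
karyotypes, (ii) the viability-corrected estimators (rates, map distance,
intervals), and (iii) a seeded Monte-Carlo simulator so every estimator can
be validated by closed-loop parameter recovery. The raw published oocyte and
progeny counts ship as plain-text fixtures; all percentages are always
recomputed from counts, never stored.

## The segregation model

A karyotype is decomposed into *units*: an X pair, a free 4 pair, a Y, and
monovalent compounds. One meiosis is modelled at the whole-chromosome
(reductional, meiosis I) level — no chromatids, because every rate of
interest is a meiosis I rate:

1. **Exchange status.** An exchange-competent X pair fails to cross over with
   probability `p_nonexchange_X` (spontaneously 5–10%; the package default is
   0.075). A balancer heterozygote (`FM7`) never exchanges; an inversion
   heterozygote (`In(1)dl-49`) is modelled as competent with a high
   nonexchange probability (0.95 in the presets) rather than as a separate
   mechanism.
2. **Heterologous engagement.** Each configured heterolog pair (e.g.
   `XX|Y`, `C4|XX`, `44|C1`, `C1|C4`) co-orients with its probability from
   `p_hs`; pairs involving the X pair apply only in nonexchange meioses.
   An engaged pair goes to opposite poles, ovum side chosen at random.
3. **Default segregation.** Unengaged bivalents and the X/4 pairs disjoin
   (one homolog per ovum); an unengaged monovalent enters the ovum with
   probability exactly 0.5.

`gamete_distribution()` returns the exact class probabilities; nothing here
is sampled. Two parameterization choices deserve comment:

* **Residual independence, not residual co-migration.** For two monovalent
  heterologs the non-engaged fraction segregates *independently*, so the null
  (`q = 0`) gives the classical quarters — both compounds, neither, or one of
  each with probability 1/4 each. Consequently the observable HS rate (the
  single-compound fraction) is `(1 + q)/2`, and matching an observed rate of
  97.1% means a co-orientation probability of `q = 0.942`. The preset
  parameters are stated on this scale.
* **Orientation equals segregation.** Cytological biorientation classes at
  metaphase I arrest are drawn from the same distribution as segregation
  outcomes (`hs_orientation_prob()`), which is exactly the concordance claim
  the estimators are designed to test.

Unsupported configurations (a third single X, two Ys, odd numbers of free 4s)
fail with an explicit error rather than being silently misclassified.

## Viability and the correction factor

`viability_model()` is an ordered first-match rule list over zygote element
doses: aneuploidy of a major arm, nullo-X, triplo-X, YY-without-X, nullo-4
and dose ≥ 4 of chromosome 4 are lethal; triplo-4 is viable; haplo-4 zygotes
("minute") get `v_minute`. `v_minute = 0` (the default) expresses a scoring
convention rather than outright lethality: minute flies exist but are too
poorly viable to count on, so an *exceptional* minute class is treated as
unrecovered, while minutes inside the bulk normal classes are scored along
with everything else. XYY males (X dose 1, Y dose 2) are viable.

`correction_factor()` derives the multiplier for exceptional counts from the
cross design and this model, with no per-genotype constants: it is the ratio
of mean recovery of the scored reference classes to mean recovery of the
exceptional classes. Three regimes emerge:

* XXY crosses: each exceptional ovum (XX or Y) survives only one of the two
  sperm genotypes → factor **2**.
* Crosses where one of the two HS products is additionally unrecoverable —
  the minute `XXY; haplo-4` class, or (for the lone attached-X female) the
  `4,4` ovum whose survivors carry no maternal marker and cannot be
  attributed — → factor **4**.
* Double-compound females crossed to compound-bearing males: every scored
  class, exceptional or not, survives exactly one sperm class in four, so
  the losses cancel → factor **1**.

The published correction footnotes are recovered as consequences, and
toggling the assumptions moves the factor (recoverable minutes drop 4 to 2;
removing sex-chromosome lethality drops 2 to 1), which the tests assert.

## Estimators

* `cytological_rates()` — configuration percentages over the scored total
  `single_mass + one_plus_out`; subset columns (`compound_out`, `hs_config`)
  are never added to the denominator. This convention reproduces every
  printed cytological percentage, and sidesteps the ambiguity of which
  column an HS configuration was found in. Integer percent, half away from
  zero.
* `genetic_hs_rate()` — corrected rate `F·x / (normal + F·x + other −
  paternal NDJ)`. Paternal nondisjunction progeny are not products of the
  female's meiosis and leave the denominator; maternal recombinants stay,
  uncorrected (no viability correction for recombinants is applied anywhere,
  as none is defensible from the crosses). Reported at the table's printed
  precision (0 or 1 decimals, half away from zero).
* `map_distance()` — `100 · rec / (normal + F·x + rec)` in cM, one decimal;
  recombinant counts are not multiplied. On the packaged inversion-cross
  breakdown (25 recombinants) this yields 0.6 cM; this denominator (NDJ
  doubled, paternal exceptions excluded) is the only convention among the
  plausible candidates that reproduces that value.
* `wilson_interval()` — the Wilson score interval, implemented directly and
  cross-checked in the tests against an independent implementation.
* **Interval for corrected rates.** The Wilson interval is computed on the
  *raw* scored exceptional proportion `e` and pushed through the monotone
  correction map `r = F·e / (1 + (F − 1)·e)`. Applying Wilson directly to
  the inflated counts would treat `F·x` as real observations and understate
  the variance (delta-method coverage ≈ 84–91% for F = 2); the transformed
  interval is exact-monotone and has nominal coverage, which the recovery
  experiment verifies empirically.
* `compare_rates()` — two-sided Fisher exact test on the 2×2 of rounded
  corrected counts plus a Wilson-overlap flag. The source data make only an
  informal concordance claim; the exact test is this package's
  operationalization, chosen because several exceptional counts are tiny.
  One genotype needs care: in the attached-4 monovalent stock the only HS
  configurations seen down the microscope are compound-versus-autosome
  malorientations whose products are lethal, so the genetically comparable
  cytological count is the `hs_recoverable` fixture column (0 for that
  genotype), not the raw `hs_config`.

One reproduction caveat: for the balancer XXY row the packaged counts
(1356 normal, 1077 exceptional, correction 2) give 61.4% at one decimal,
while the source table prints 61.3% for these literature-derived counts. The
package reports its own arithmetic and does not force the printed value.

## The simulator

`simulate_cross()` draws ovum class, sperm class, a survival Bernoulli and a
phenotype class per zygote, accumulating until the target number of
surviving *scored* progeny is reached — flies are what get counted, not
attempted zygotes. `simulate_oocytes()` draws metaphase orientation from the
segregation distribution and, at prometaphase, an independent movement
indicator; movement probabilities are free parameters (defaults are neutral
at 0.5) because the data constrain frequencies, not a mechanism, and
per-oocyte correlation between movement and eventual orientation is assumed
absent. Recombination is a single interval probability applied to the X
transmitted by an exchange meiosis — no interference, no double-crossover
classes, since only one interval is ever scored. A run uses one global RNG
stream; the seed is recorded on the output and the caller's RNG state is
restored afterwards.

What the generator deliberately does not emulate: fecundity differences
between genotypes, egg-laying time courses, scoring error, and any
correlation structure between oocytes of one female. Passing recovery tests
therefore demonstrate estimator correctness under the model's sampling
assumptions, not robustness to those real-data features.

## Verification by parameter recovery

`recovery_report()` closes the loop: simulate at a known rate, estimate with
the derived correction, check bias and interval coverage. The packaged
experiment uses the balancer-XXY design (nonexchange certain, factor 2) at
true rates 2%, 65% and 97% with 5,000 scored progeny per cross: bias is
bounded at 200 replicates per grid point and coverage at 500 replicates per
grid point (a coverage proportion needs the larger replicate count to be
informative; 200 replicates leave ±1.5 points of pure Monte-Carlo noise on
it). Exact computation of the interval's coverage under the binomial sampling
model gives 0.949–0.953 at all three rates. Map-distance recovery simulates
a 10 cM interval at 20,000 progeny and requires agreement within three
binomial standard errors (±0.64 cM). These problem sizes run the whole suite
in well under a minute on a laptop while leaving the stochastic checks
adequately powered.

## Numerical and degenerate-input choices

* Rounding everywhere is half-away-from-zero at the printed precision,
  implemented by truncation to avoid banker's rounding surprises.
* Distribution normalization is asserted to 1e-12 after every construction.
* Empty samples (zero scored oocytes, zero corrected denominator) raise
  explicit errors, as do designs in which no exceptional class is
  recoverable.
* Probabilities of heterolog pairs applicable to the same karyotype may not
  sum above 1; this is checked per exchange branch.
* Triplo-4 viability is not stated by the source crosses; it defaults to 1
  (the quadrupling convention implicitly assumes the compound-4-bearing
  exceptional males survive), and is configurable through the rule list.
* YY ova never arise in the XXY model (the Y is a monovalent), matching the
  stock scheme that avoids XYY fathers.

## Worked example

```{r example}
t2 <- load_table2()
estimate_genetic_rates(t2$progeny)[, c("genotype", "factor", "hs_rate_pct",
                                       "map_cM")]
concordance_test("In1_XXY")$p_value
```
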