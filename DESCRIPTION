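Package: hetseg
Title: Heterologous Segregation and Secondary Nondisjunction in Drosophila Female Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward model and estimators for aberrant chromosome segregation in
    Drosophila melanogaster female meiosis I. Represents karyotypes carrying
    compound chromosomes, balancers and extra Y chromosomes; computes exact gamete
    class distributions under exchange-dependent X segregation, secondary
    nondisjunction and heterologous co-orientation; derives viability correction
    factors from a zygote survival model; and estimates viability-corrected
    heterologous segregation rates, recombination map distances and confidence
    intervals from progeny count tables. A seeded Monte-Carlo simulator generates
    oocyte configuration counts and progeny tables with the same structure, so
    every estimator can be checked by closed-loop parameter recovery. Ships the
    published count tables as plain-text fixtures and a small command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
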