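Package: karyosim
Title: Deterministic Population Dynamics of Chromosomal Rearrangements
    Under Spindle-Assembly-Checkpoint Gamete Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the population dynamics of chromosomal fission and
    fusion variants in one or two ecological niches. A combinatorial model of
    spindle-assembly-checkpoint (SAC) kinetochore attachment in meiosis II
    yields the gamete and zygote classes produced by a rearrangement
    heterozygote and hence its fertility penalty; a deterministic discrete-time
    engine propagates wild-type homozygote, heterozygote and variant-homozygote
    class sizes under exponential-capped, Gompertz or discrete-logistic growth,
    full Hardy-Weinberg redistribution each step, carrying-capacity
    enforcement, and threshold- or density-driven migration between niches
    with per-genotype survival factors and stop/resume windows. Reports times
    to carrying capacity, extinction and steady state, and ships a library of
    declarative benchmark scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
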