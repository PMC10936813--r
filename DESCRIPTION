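Package: meiodsb
Title: Simulation and Analysis of Meiotic Spo11 DSB Interference and Hotspot Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying meiotic DNA double-strand break (DSB)
    interference in budding yeast. Provides a stochastic per-cell simulator of
    Spo11 DSB formation under a primed-domain model with Tel1-mediated
    distance-dependent suppression and genotype-dependent prophase-exit
    windows; the coefficient-of-coincidence interference statistic
    (-log2 observed/expected double cuts) with probe corrections, timepoint
    averaging and replicate comparison; CC-seq style hotspot calling from
    per-base break maps (Hann smoothing, HpM thresholding, merging and
    background-calibrated NormHpM strengths); and genome-wide comparative
    analyses (hotspot correlations, per-hotspot log2 ratios, local-regression
    smoothing, centromere-anchored 50 kb binning and correlation against a
    chromosomal association-timing track).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
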