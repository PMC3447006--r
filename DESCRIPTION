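Package: ploidysel
Title: Simulation and Analysis of Divergence Selection Experiments Across Ploidies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation and analysis of truncation-selection
    breeding experiments in diploid, autotetraploid and newly synthesized
    (neo)tetraploid plants. Simulates additive polygenic traits under disomic
    or tetrasomic inheritance with optional double reduction, maternal
    half-sib family structure, ploidy-specific sterility and large
    generation-to-generation environmental blocks. Provides estimators of
    per-generation and cumulative selection differentials, control-corrected
    responses, realized heritability with confidence limits, Wright's
    path-method inbreeding coefficients from pedigrees, coefficients of
    variation with noncentral-t confidence intervals, and flow-cytometry
    2C DNA content ratios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
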