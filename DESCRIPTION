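Package: lipidims
Title: Direct-Infusion Mass-Spectrometry Lipidomics Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for shotgun (direct-infusion) mass-spectrometry
    lipidomics of paired clinical samples. Annotates centroided peak lists
    against a lipid library by adduct m/z within a ppm tolerance with
    mode-specific isobar priority rules, applies signal-quality filters
    (zero values, signal-to-noise against blanks, sample presence, and
    QC dilution-series linearity), normalizes signals to per-mille relative
    abundance, screens analytical outliers by principal component analysis,
    and runs paired cross-compartment and unpaired motility-group t-tests
    with lipid-class aggregation and volcano tables. Includes a fully seeded
    synthetic cohort generator (three compartments, blanks, QC dilution
    series, spiked effects) so every stage is testable with known ground
    truth, plus readers and writers for the plain-text CSV/TSV interchange
    formats and a single-call pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
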