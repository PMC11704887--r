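Package: fadesame
Title: Single-Value fMRI Scores of Memory-Network Preservation and
    Environmental Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses task-fMRI single-value scores of
    memory-network preservation in older adults. Provides a synthetic
    cohort generator (encoding-task sessions, voxelwise contrast maps on a
    toy grid, leisure-activity questionnaire responses with
    missing-completely-at-random gaps, demographics), scoring of the
    Lifetime of Experiences Questionnaire into an environmental-enrichment
    score, first-level GLM estimation of novelty and subsequent-memory
    contrasts, FADE and SAME scores against a young reference cohort,
    Little's MCAR test, full-information maximum-likelihood regression
    with standardized coefficients, and an end-to-end analysis pipeline
    with covariate screening, subgroup models and diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
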