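Package: hsclone
Title: Clonal Analysis of Single Hematopoietic Stem Cell Transplantation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell transplantation assays of
    hematopoietic stem cells (HSCs) read out as longitudinal five-lineage
    peripheral-blood chimerism. Converts raw flow-cytometry gate counts to
    donor chimerism, classifies every clone into a functional taxonomy
    (HSCs, myeloid-restricted repopulating progenitors and stem cells,
    latent-HSCs, others, non-reconstituting) from its primary and linked
    secondary time series, and combines per-fraction clonal outcomes with
    sorting-fraction frequencies to estimate the functional composition of
    the phenotypic HSC compartment, absolute cell-type frequencies per
    million bone-marrow cells, age-related fold changes, bootstrap
    confidence intervals and a composition chi-square test. Includes a
    synthetic-cohort generator emulating the study design (binomial gate
    sampling, recipient death censoring, secondary transplants) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
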