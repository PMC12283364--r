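Package: cloneclock
Title: Colony-Level Somatic Phylogenies, Mutational Signatures and
    Mutation-Burden Models for Normal Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome analyses of single-cell-derived
    hematopoietic colonies: somatic variant filtering from per-colony
    read counts, maximum-parsimony phylogeny reconstruction with
    per-branch mutation assignment, sensitivity correction and
    ultrametric molecular-clock scaling of trees to chronological age,
    96-channel mutational-signature fitting and de novo extraction,
    Poisson identity-link mixed-effects modelling of mutation burden
    against age and mutagen exposure, and clonal-architecture metrics
    (expanded clades, driver overlays, clone growth). Includes a
    synthetic-cohort generator emulating clock-like mutation accrual,
    chemotherapy mutation pulses, driver-clone expansions, germline
    variants, culture artifacts and binomial read sampling, so the whole
    pipeline is testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
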