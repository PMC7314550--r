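Package: ptvburden
Title: Burden of Ultra-Rare Protein-Truncating Variants and Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the association between the germline burden of
    ultra-rare protein-truncating variants (PTVs) and human lifespan and
    healthspan. Reads annotated exome variant tables or VCF files with
    ANN-style functional annotations, applies site-level quality and
    frequency filters, classifies protein-truncating effects, and computes
    per-individual burden by minor-allele-frequency bin. Provides a Cox
    proportional-hazards fitter (Efron ties) for follow-up survival and a
    Gompertz-baseline proportional-hazards maximum-likelihood model for
    age-scale morbidity, together with Kaplan-Meier curves, log-rank tests,
    translation of log-hazard coefficients into years of life, a somatic
    mutation accumulation model, and gene-level constraint and burden
    statistics (PTV versus synonymous contingency tests, split-cohort
    burden scans, the 50-bp nonsense-mediated-decay rule). A synthetic
    cohort generator reproduces the statistical structure of a large
    biobank exome study so that the whole pipeline can be exercised and
    calibrated without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    survival,
    withr,
    flexsurv,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
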