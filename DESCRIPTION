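Package: cnamlrisk
Title: Genotype Risk Stratification and Post-Remission Outcome Modelling for
    Cytogenetically Normal AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostication of de novo cytogenetically normal acute
    myeloid leukemia (CN-AML) in younger adults from gene-panel mutation data.
    Implements deterministic genotype classification (five NPM1/FLT3-ITD/DNMT3A
    combination categories, gene-only ELN 2017 risk, and a DNMT3A-modified ELN
    risk), clonal-architecture calling from variant allele frequencies,
    endpoint construction (leukemia-free, event-free and overall survival, with
    optional censoring at transplantation), self-contained Kaplan-Meier,
    log-rank and Cox proportional-hazards estimation, a parametric
    cause-specific multistate model of post-remission outcomes with
    state-occupancy ("sediment plot") prediction under transplant-at-CR1
    versus no-transplant strategies, Harrell concordance evaluation with
    paired bootstrap model comparison, and a reproducible synthetic cohort
    generator for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
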