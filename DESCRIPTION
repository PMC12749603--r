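Package: necrosig
Title: Derivation and Scoring of a Tumor Necrosis Gene Expression Signature
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to derive a directional gene-expression signature from a
    two-group (tumor necrosis present/absent) comparison using a SAM-style
    modified t-statistic with permutation false-discovery rates, to compute
    per-sample directional sum-scores, and to carry the score through
    association testing, disease-specific survival analysis (Kaplan-Meier,
    log-rank, Cox proportional hazards), signature-panel scoring and
    group-wise somatic-mutation contrasts. Includes a synthetic cohort
    generator with planted differential genes, score-linked survival and
    group-dependent mutation rates for end-to-end recovery testing, plus
    readers and writers for expression matrices, clinical tables, GMT gene
    sets and MAF mutation files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
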