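Package: secrank
Title: Ranking Fasting- and OGTT-Derived Insulin Secretion Indices by
    Power to Detect Genetic Effects on Beta-Cell Function
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calculators for twelve fasting-, OGTT- and IVGTT-derived
    indices of insulin secretion (HOMA-B, insulinogenic indices, corrected
    insulin response, oral disposition index, first-phase estimate, AUC
    ratios, Matsuda sensitivity index, insulin clearances, acute insulin
    response), confounder-adjusted least-squares association of each index
    with SNP genotypes under an additive model, post-hoc power and least
    significant number (lsn) from the noncentral F distribution, lsn-based
    rank aggregation over SNP panels with exact Wilcoxon rank-sum
    comparison against a reference index, and a seeded synthetic cohort
    generator emulating the statistical structure of a type-2-diabetes
    risk cohort so the whole pipeline is testable without subject-level
    data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
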