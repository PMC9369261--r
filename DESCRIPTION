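Package: refstab
Title: Reference Gene Stability Ranking and Relative Quantification for
    RT-qPCR Cq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects stably expressed reference (housekeeping) genes from
    RT-qPCR crossing-point (Cq) tables stratified by tissue region and
    genotype. Implements the four standard stability estimators (comparative
    Delta Ct, geNorm, BestKeeper, NormFinder) from their original
    formulations, combines them into a comprehensive ranking by the geometric
    mean of per-method ranks, sweeps the ranking over both design axes
    (across regions within genotype, across genotypes within region), and
    compiles a weighted reference-gene panel. Target-gene expression is then
    quantified relative to the panel (2^-dCq) and compared between genotypes
    with Shapiro-Wilk normality checks and two-sample t-tests. A seeded
    synthetic-data generator reproduces the factorial study design (nine
    brain regions x two genotypes x biological x technical replicates) with
    known ground truth, so every pipeline stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
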