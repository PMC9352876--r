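Package: convergex
Title: Convergent Drug-Effect Transcriptomics: Differential Expression
    Meta-Analysis, TWAS Regression, Cell-Type Enrichment and Constraint
    Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying convergent transcriptomic drug targets
    across cell types and treatments. Implements gene-wise Wald-test
    differential expression under a plate + buffer + treatment design with a
    low-abundance filter and Benjamini-Hochberg FDR control; Stouffer's
    Z-score meta-analysis of per-condition statistics across condition sets;
    weighted and unweighted regression of TWAS gene Z-scores on drug-effect
    Z-scores controlling for gene length and GC content; one-sample Z-test
    enrichment of gene sets in cell-type average-expression profiles; and
    comparison of loss-of-function constraint (gnomAD-style o/e) between
    differentially expressed genes and propensity-score-matched background
    genes. A seeded synthetic-data generator produces count matrices, gene
    annotation, TWAS statistics and cell-type profiles with known ground
    truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
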