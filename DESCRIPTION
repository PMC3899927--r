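Package: fcrank
Title: Fold Change Rank Ordering Statistics for Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed genes between two biological
    conditions using fold change rank ordering statistics (FCROS). Log2 fold
    changes are computed for pairwise control/test sample comparisons, ranked
    within each comparison with midrank tie handling, and summarised per gene
    by a trimmed mean of standardized ranks. A normal model fitted to these
    rank means yields a per-gene probability (f-value) that directly encodes
    down-regulation, no change, or up-regulation, avoiding per-gene multiple
    testing. Includes a two-batch variant requiring no inter-batch
    normalization, baseline comparator statistics (fold change ranking,
    pooled t-test, weighted average difference), a seeded simulator of
    two-condition expression matrices with known ground truth, and evaluation
    tools (confusion counts, rank AUC, subsampling stability scores,
    reproducibility counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
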