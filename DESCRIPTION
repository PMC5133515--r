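Package: wblrt
Title: Weighted-Burden Likelihood Ratio Tests for Rare-Variant Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level case-control association tests for exome sequencing
    data based on a threshold-maximized Bernoulli likelihood ratio statistic
    over weighted burden scores. Implements the plain LRT, the
    direction-weighted LRT-DIR (per-variant effect signs refit inside every
    permutation replicate), and the annotation-weighted LRT-BS (e.g.
    protein-binding-site weights 10/5/1), with gene-specific two-stage
    adaptive permutation p-values, CMC and C-alpha comparator tests run on
    the same permutation streams, a synthetic case-control cohort simulator
    for power and type-I-error studies of weighting schemes, and
    QQ-plot/genomic-inflation reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
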