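Package: brca2del
Title: Deletion Signature Screening for BRCA2-Mutant Breast Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-stage inference pipeline establishing 13q/14q deletions as
    a marker of BRCA2-mutant breast tumors: empirical-Bayes moderated-t
    signature discovery with Benjamini-Hochberg selection, a t-weighted
    expression score evaluated by ROC/AUC, preranked gene-set enrichment over
    cytogenetic-band positional sets with permutation-based NES and
    family-wise error rates, array-CGH gain/loss calling with cumulative
    aberration frequencies and common-region-of-overlap extraction, B-allele
    frequency allelic-imbalance flagging, and a two-color FISH spot-count
    deletion test evaluated by exact contingency statistics. A synthetic
    cohort generator provides ground-truth two-group cohorts with hemizygous
    band deletions attenuated by tumor-cell fraction, driving correlated
    expression reduction, CGH log-ratio shifts, BAF splitting and reduced
    red-spot counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    fgsea,
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, DifferentialExpression, GeneSetEnrichment,
    GeneExpression, Classification
RoxygenNote: 7.3.3
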