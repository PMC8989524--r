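Package: chromsig
Title: Gene-Level Chromatin Signatures from Multi-Mark ChIP-Seq in Male and
    Female Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments binarized multi-mark histone-PTM ChIP-seq signal with a
    joint multivariate Bernoulli hidden Markov model learned from male and
    female samples together, groups emission states into five functional
    categories, assigns each gene one of sixteen chromatin signatures, and
    integrates the signatures with expression (TPM, tissue-specificity tau,
    sex-biased expression calls). Provides male/female signature-transition
    summaries, per-region (autosome, pseudoautosomal and sex-determining
    region) histone-mark coverage, covariate-matched subsampling permutation
    tests on signature proportions, and signature-by-location linear models of
    expression. A synthetic-data generator emulates the full input structure
    (six marks, two sexes, two replicates, transposon and gene-age labels)
    with recorded ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
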