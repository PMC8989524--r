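# chromsig

Gene-level chromatin signatures from multi-mark histone-PTM ChIP-seq in male
and female genomes.

`chromsig` is an R package for epigenomics researchers studying how histone
post-translational modifications (PTMs) reorganise between sexes — in
particular in haploid UV sex-determination systems, where a U or V
chromosome carries a small non-recombining sex-determining region (SDR)
embedded in a large recombining pseudoautosomal region (PAR). It takes
binned, binarized ChIP-seq signal for several marks in two sexes, learns a
single joint chromatin-state model, collapses states into gene-level
**chromatin signatures**, and quantifies how signatures relate to
expression, to sex-biased genes, and to genomic location (autosome / PAR /
SDR).

## The model

Observations are per-bin presence/absence calls for M histone marks at
200-bp resolution, obtained from a Poisson background test
(call = 1 iff P(X ≥ x | λ) ≤ 10⁻⁴ with λ the control-scaled background,
floored at 1). A K-state hidden Markov model with multivariate Bernoulli
emissions is fitted by Baum–Welch to male and female genomes **jointly**
(each chromosome of each sex an independent sequence sharing one parameter
set):

> state k emits mark m with probability e\_km;
> P(x\_t | z\_t = k) = ∏\_m e\_km^{x\_tm} (1 − e\_km)^{1 − x\_tm}

Bins are decoded by forward–backward posterior argmax, and the number of
states is chosen by refitting smaller models and tracking the worst Pearson
correlation between reference and best-matching emission vectors (the
study design this package follows selects K = 12 from a 17-state
reference).

States are grouped into five categories — Permissive 1 (TSS marks
H3K4me3/H3K9ac/H3K27ac), Permissive 2 (H3K36me3), Mixed, Silent
(H3K79me2/H4K20me3), Null — and each gene's signature S1–S16 is the subset
of non-null groups overlapping its body (S16 = the null signature: genes
overlapping nothing but the null state). Downstream statistics include the
tissue-specificity index tau, sex-bias calls (|FC| ≥ 2, FDR < 0.05, TPM > 1
in the favoured sex), male/female signature-transition tables, per-region
mark coverage, covariate-matched subsampling permutation tests on signature
proportions (Pearson chi-square observed vs. pool, empirical
p = (b+1)/(n+1), with exact TE-prevalence matching or a ±25%-of-median
expression window), and linear models of log2(TPM+1) with
signature × location interactions (S1 reference level).

A fully ground-truthed synthetic-data generator
(`generateDataset()`) emulates the complete input structure — 6 marks × 2
sexes × 2 replicates plus controls, PAR/SDR layout, TE and gene-age labels,
expression coupled to chromatin class, a ~1.5% minority of sex-biased genes
— so the entire pipeline is exercisable and testable offline.

## Worked example

```r
library(chromsig)

dataDir <- file.path(tempdir(), "toy-data")
outDir  <- file.path(tempdir(), "toy-run")

## a complete ground-truthed miniature study (2 Mb, ~1000 genes)
truth <- generateDataset(syntheticConfig(seed = 1), dataDir)

## binarize -> joint 12-state HMM -> signatures -> expression -> statistics
res <- runPipeline(runConfig(dataDir, outDir, nPerm = 10000, seed = 1))

res$model
#> BernoulliHMM: K=12 states, 6 marks, logLik=-24320.59 (200 iterations)

head(signatureProportions(res$signatures$female)[
  order(-signatureProportions(res$signatures$female)$proportion), ], 4)
#>    signature count proportion
#> 2         S2   140  0.1398601
#> 1         S1   136  0.1358641
#> 3         S3   126  0.1258741
#> 16       S16    98  0.0979021

read.delim(file.path(outDir, "transition_summary.tsv"), comment.char = "#")
#>          subset n_genes fraction_changed
#> 1           all    1001        0.2577423
#> 2   male_biased       8        0.5000000
#> 3 female_biased       6        0.5000000
#> 4      unbiased     987        0.2543060
#> 5           par     160        0.3312500

res$permutations$par_vs_autosome_female
#> PermutationResult: observed chi-square 97.840, p = 9.999e-05
#>   (matching NONE, n_perm 10000, seed 1)
```

Reading the output: S1–S3 (activation-associated signatures built from the
two permissive groups) dominate the gene set, S16 marks genes devoid of
assayed marks. Sex-biased genes change signature between males and females
far more often (0.50) than unbiased genes (0.25), and PAR genes sit in
between (0.33) — the planted excess of repressive chromatin on the PAR is
rejected against the autosomal background at p ≈ 10⁻⁴ by the subsampling
permutation test. `evaluateAgainstTruth()` scores any stage of the run
against the generator's recorded truth.

All result tables are tab-separated with a header comment naming the
producing stage and a config hash; `run.log` records versions, seed and
configuration. A thin command-line wrapper over the same functions is
installed at `inst/scripts/chromsig.R`
(`Rscript chromsig.R simulate --out DIR`, `... run-all --data DIR --out DIR`).

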