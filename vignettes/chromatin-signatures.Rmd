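---
title: "Gene-level chromatin signatures from multi-mark ChIP-seq: models and methods"
author: "chromsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level chromatin signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The scientific problem

In organisms with UV sex determination (many brown algae and mosses), sex is
expressed in the haploid phase: a U chromosome yields a female, a V
chromosome a male. The male and female sex-determining regions (SDRs) are
small and non-recombining, while most of the sex chromosome — the
pseudoautosomal region (PAR) — recombines and is shared. Sexual dimorphism is
nonetheless driven largely by autosomal sex-biased gene expression, and a
central question is whether histone post-translational modifications (PTMs)
reorganise between males and females at sex-biased genes and on the sex
chromosome.

`chromsig` implements the full quantitative chain used to address that
question with six histone PTMs (H3K4me3, H3K9ac, H3K27ac, H3K36me3,
H3K79me2, H4K20me3) profiled by ChIP-seq in near-isogenic male and female
lines, paired with RNA-seq from the same cultures:

1. binarize per-mark read tracks at 200-bp resolution against a control,
2. learn **one joint hidden Markov model** over both sexes and decode
   per-sex chromatin-state segmentations,
3. group emission states into five functional categories and collapse each
   gene's overlapping categories into one of **16 chromatin signatures**,
4. integrate expression (TPM, expressed/silent calls, the
   tissue-specificity index tau, sex-bias calls from a differential
   expression table),
5. compare sexes (signature transition tables, sex-specific mark domains,
   per-region mark coverage) and regions (PAR, SDRs, autosomes) with
   covariate-matched subsampling permutation tests and
   signature-by-location linear models.

A synthetic-data generator reproduces the statistical structure of the real
inputs with recorded ground truth, so every stage is testable end to end
without any download.

# Models and procedures

## Binarization

Reads are counted into fixed 200-bp bins by their 5' start (deterministic,
no fragment-length estimation; strand is ignored throughout). For bin $i$
with IP count $x_i$ and control count $c_i$, the expected background is
$\lambda_i = c_i \cdot \frac{\sum x}{\sum c}$ (the global mean IP per bin
when no control is given), floored at `lambdaMin = 1` to avoid degenerate
zero-background calls. The mark is called present iff the Poisson upper
tail $P(X \ge x_i \mid \lambda_i)$ is at most `pThreshold = 1e-4`. These
defaults follow the standard genome-segmentation binarizer. The call is
monotone in $x_i$ by construction.

Replicates are binarized separately and combined per bin by logical OR by
default (`"and"` is available); pooling counts upstream is a third option.
OR was chosen because presence calls are sparse and conservative, so the
union recovers sensitivity without inflating the background (measured
false-positive rates stay below 1%).

Signal extraction scaling (SES) is provided for display-ratio tracks: bins
are ordered by ascending IP, the rank maximising the gap between cumulative
control and cumulative IP fractions defines the background segment, and the
control is scaled by the IP/control ratio over that segment. SES is **not**
applied before binarization — the binarizer's own total-count scaling plays
that role — matching the way the corresponding tools are normally composed.

## The joint Bernoulli-emission HMM

Observations are rows of a bins × marks 0/1 matrix. A $K$-state model has
per-state, per-mark emission probabilities $e_{km}$ (marks conditionally
independent given the state), a row-stochastic transition matrix and an
initial distribution. Every chromosome of every sample is an independent
observation sequence, and **male and female sequences are pooled into one
training set**, so both sexes share a single state vocabulary and their
segmentations are directly comparable.

Fitting is Baum–Welch with a scaled (linear-space) forward–backward pass
implemented in C++. Emissions are clipped to $[10^{-6}, 1 - 10^{-6}]$ to
prevent log-domain collapse; EM stops when the log-likelihood improves by
less than `tol = 1e-4` or after `maxIter = 200` iterations; the
log-likelihood trace is recorded and is non-decreasing (asserted to within
`1e-8` in the validity method). The forward–backward pass is verified
against exhaustive enumeration of all hidden paths on short sequences
(agreement to `1e-9`).

Two initialisations are available:

* `init = "uniform"` (the `fitHMM()` default): emissions drawn uniformly in
  $[0.1, 0.9]$ from the seeded generator, uniform transitions and initial
  distribution. Simple, but on sparse combinatorial data EM started this way
  often spends several states modelling the large all-zero background and
  merges rare mark combinations; the outcome varies across seeds and is not
  predicted by the final likelihood.
* `init = "patterns"` (the pipeline default): emission rows are seeded from
  the $K$ most frequent distinct observed mark patterns (mapped from
  \{0,1\} to \{0.1, 0.9\}), in the spirit of the information-based
  initialisation of the field's segmentation tools. This anchors each
  combinatorial state at an actually-observed pattern and makes the fit
  essentially deterministic across seeds on the synthetic data.

Decoding assigns each bin the state with the highest forward–backward
posterior (ties broken toward the lowest state index); Viterbi decoding is
available as an option and agrees with posterior decoding on
well-separated data. Consecutive equal-state bins are merged into tiles.

## Choosing the number of states

Following the study design, a reference model with `kMax = 17` states is
fitted first; for each smaller $k$ down to `kMin = 8`, every reference
state is matched to its most similar state in the $k$-state model by
Pearson correlation of emission vectors (constant rows are defined to have
correlation 0). The chosen $K$ is the smallest $k$ whose worst-recovered
reference state still correlates at or above `similarityFloor = 0.9`; the
floor is a free parameter because the original criterion is qualitative.
When no $k$ qualifies the reference `kMax` is kept. The pipeline defaults
to the study's $K = 12$ directly; selection is run when `K = NULL`.

## From states to the 16 signatures

Emission states fall into five groups: *Permissive 1* (TSS-proximal
activation marks H3K4me3/H3K9ac/H3K27ac), *Permissive 2* (gene-body
H3K36me3), *Mixed* (activation- plus repression-associated marks),
*Silent* (H3K79me2 and/or H4K20me3) and *Null* (no assayed marks). For a
12-state model ordered as in the study, the built-in map is E1–E3 →
Permissive 1, E4–E5 → Permissive 2, E6–E8 → Mixed, E9–E11 → Silent, E12 →
Null. For refitted models, whose states carry no intrinsic order,
`inferStateGroups()` classifies each state from its emission profile using
a presence cutoff of 0.5 per mark role (TSS marks, H3K36me3, repressive
marks); if no state is devoid of marks the flattest state is forced Null so
the map always contains a null state.

A gene's **signature** is the set of non-null groups whose states overlap
its annotated body by at least `minOverlap = 1` bp (strand ignored; no
promoter flank). The null group is dropped whenever any other group is
present; a gene overlapping nothing but null-state tiles gets the null
signature S16. Subsets are numbered canonically by bitmask (Permissive 1 =
bit 0, Permissive 2 = bit 1, Mixed = bit 2, Silent = bit 3; mask $k$ →
S$k$, empty set → S16); a custom subset-to-identifier table may be
supplied. The default class labels are rule-derived — only-permissive
subsets are ACTIVATION (3), subsets mixing a permissive group with
Mixed/Silent content are MIXED (9), permissive-free subsets are REPRESSION
(3), S16 is NULL — which differs from the published figure's 5/7/3 split
(an enumeration the text does not give); the class table is therefore a
replaceable configuration, and outputs record the signature identifiers so
any class table can be applied downstream.

## Expression integration

* **TPM**: $\mathrm{TPM}_g = 10^6 \,(x_g/\ell_g) / \sum_h (x_h/\ell_h)$ per
  sample; columns sum to $10^6$ within $10^{-3}$.
* **Expressed**: per sample, the threshold is the 5th percentile of that
  sample's TPMs (linear-interpolation percentile; the source does not state
  a percentile method). A gene is expressed if it reaches the threshold in
  at least one sample (`"all"` is available; the union rule is
  config-exposed because the original choice is unstated).
* **tau**: with $\hat x_i = x_i / \max_i x_i$ over $N$ conditions,
  $\tau = \sum_i (1-\hat x_i)/(N-1)$; housekeeping iff $\tau < 0.25$,
  narrow iff $\tau > 0.75$ (strict inequalities, as printed); all-zero
  profiles give `NA`.
* **Sex bias**: consumed from a differential-expression table (the DE fit
  itself is out of scope). Male-biased iff $\log_2\mathrm{FC} \ge 1$
  (male/female orientation, stated in every output header), FDR $< 0.05$
  and mean male TPM $> 1$; female-biased symmetrically; all other genes,
  including genes absent from the table, are unbiased.

## Permutation tests and models

The proportion comparison between a target gene set (e.g. PAR genes) and a
pool (e.g. autosomal genes) uses the Pearson chi-square statistic of the
target's signature counts against pool proportions, $\sum_c (O_c -
E_c)^2/E_c$ with $E_c = N p_c$. Categories expected and observed zero are
dropped; observed counts in zero-expectation categories make the statistic
infinite and flagged. The null distribution subsamples `|target|` genes
from the pool without replacement `nPerm` times (default 100,000,
config-scalable) and recomputes the statistic against the same full-pool
proportions; the empirical p-value is $(b+1)/(n_\mathrm{perm}+1)$, never
zero. Because the statistic depends on a draw only through per-signature
counts, draws are sampled as stratified multivariate hypergeometric counts
(sequential `rhyper`), which is exactly equivalent in distribution to
index sampling and vectorises over permutations.

Matching modes: `TE_PREVALENCE` stratifies by transposable-element overlap
and fixes each draw's TE count exactly at the target's ("exactly the same
TE prevalence"); `EXPRESSION_WINDOW` restricts the pool to genes whose mean
expression lies within 25% of the target median before drawing. Matching
that cannot be satisfied is an error stating the deficit (the pipeline
reports and skips such tests rather than silently weakening them).

The expression model is ordinary least squares of $\log_2(\mathrm{TPM}+1)$
on signature (S1 reference level), location (autosome vs PAR) and their
interaction. Signature levels with fewer than two genes are dropped with a
warning; coefficients the design cannot identify (a signature present on
only one location) are reported as inestimable rather than dropped.
Benjamini–Hochberg adjustment is exposed as a validated wrapper around the
standard step-up procedure.

# The synthetic data generator

`generateDataset()` writes a complete miniature study: layout YAML, GFF3
gene models, TE BED and gene-age TSV, per-sex/mark/replicate ChIP read
BEDs plus per-sex controls, replicated count tables, a DE table written
directly from the planted effects, and truth tables. Everything is
deterministic given the config seed.

**Scale.** Four autosomes of 400 kb plus one 400-kb sex chromosome (PAR
0–320 kb, female SDR 320–360 kb, male SDR 360–400 kb; one layout carries
both SDRs, as the reference assembly does), 200-bp bins — 10,000 bins
genome-wide — and roughly 1,000 bin-aligned genes of 0.8–1.6 kb with at
least one null bin between genes (genic fraction ≈ 60%, typical of a
gene-dense genome). This size lets the whole pipeline, including fitting a
12-state model on both sexes and 100,000-draw permutation tests, run in
about a minute on one CPU; the test suite scales `nPerm` to 2,000 and EM to
150 iterations for speed.

**Chromatin truth.** Each gene draws a signature class from
region-dependent probabilities mirroring the study's headline structure:
autosomes ≈ 25% repressive (REPRESSION + NULL), PAR ≈ 52%, female SDR ≈
85%, male SDR ≈ 53%. Within a class a concrete group subset is drawn
uniformly, and the gene body is painted with contiguous runs of states
from each of its groups; intergenic bins and the whole gene are E12 for
null-signature genes. SDR genes are null-signature and silent in the sex
that lacks that chromosome region. Painting states gene-wise (rather than
simulating from a transition matrix) makes the recorded per-gene truth
*exactly* recomputable from the painted states via the package's own
intersection/assignment path — an internal consistency oracle the tests
assert.

**Sex differences.** A fraction of non-SDR genes (default 1.5%, matching
the published 268/18,462) is sex-biased with planted $|\log_2\mathrm{FC}|
\in [2, 4]$; the favoured sex gets an activation signature and, with
probability 0.4, the disfavoured sex is moved to a mixed/repressive
signature (the published ≈38% transition rate at sex-biased genes).
Unbiased genes redraw their male signature with probability 0.10 on
autosomes and 0.32 on the PAR (the published 32% PAR transition rate),
mostly without expression change. TE overlap is planted at 80% (PAR) vs
36% (autosomes); young-gene fractions at 53% (PAR) vs 22% (autosomes).

**Reads.** For each sex/mark/replicate, per-bin read counts are Poisson
with rate interpolating between `depthBackground = 1` and `depthEnriched =
24` by the true state's emission probability; read starts are uniform
within the bin. The enriched depth reflects deep sequencing (tens of
millions of reads per IP in the emulated study): at the binarizer's fixed
defaults, enriched bins must clear roughly 8–15 reads to be called, so a
mean enriched depth near 8 would leave per-replicate sensitivity below
0.5 and no decoder could recover the states; at 24 the post-OR
sensitivity is 0.8–0.87 with a sub-1% false-positive rate, and recovery
becomes a property of the method rather than of read-depth luck. Controls
are flat Poisson(1) tracks. Expression is log-normal per signature class
(activation high, mixed intermediate, repressive/null low), counts are
Poisson around length-scaled expression, and the DE table carries the
planted fold changes with small noise (unbiased genes get adjusted p
uniform on [0.2, 1], so a zero biased fraction yields no calls).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: mappability and GC bias, fragment-length
effects, duplicate reads, peak-shape differences between narrow and broad
marks, overdispersed (non-Poisson) counts, correlated replicates,
multi-tissue expression atlases for tau (the pipeline computes tau across
the four synthetic samples), intron/exon structure, and any real linkage
between TE content and chromatin beyond the planted marginals. Results on
real data additionally depend on alignment and peak-calling choices that
are explicitly out of scope.

# Measured recovery on the default synthetic data

The end-to-end tests (fixed seed, default generator, pipeline with
`init = "patterns"`) compute: gene-level signature agreement with truth
≈ 0.93 per sex; bin-level state accuracy ≈ 0.87, rising above 0.93 when
the two identical-emission H3K36me3 states are counted as one — the truth
deliberately contains two states with the same emission profile (as the
emulated study's model does), and no decoder can distinguish bins painted
with one from the other. Planted PAR repression excess rejects at
$p < 0.01$ under both unmatched and TE-matched permutation in both sexes,
and planted sex-biased genes show a higher male/female signature-transition
fraction than planted unbiased genes. Null calibration of the permutation
p-values (target subsampled from the pool) passes a KS uniformity check at
$\alpha = 0.01$ over 200 repetitions, with a rejection rate at
$\alpha = 0.05$ inside [0.03, 0.07] over 500 repetitions.

# Numerical choices and degenerate inputs

* Coordinates: GRanges (1-based, closed) internally; GFF3 (1-based
  inclusive) and BED (0-based half-open) converted at the file boundary.
  Gene region class is assigned by the midpoint
  $\lfloor(\mathrm{start}_0+\mathrm{end}_0)/2\rfloor$ against the layout.
* Emission clipping $10^{-6}$; posterior ties toward the lowest state
  index; per-sequence scaling keeps the forward pass in linear space.
* SES: if the background segment has zero control mass the factor falls
  back to total-IP/total-control; ratio bins with zero control are capped
  at 50 (display only).
* `chiSquareStat` drops 0-expected/0-observed categories and returns a
  flagged `Inf` when a target category is absent from the pool.
* All-zero expression profiles give `NA` tau; all-zero count samples give
  zero TPM with a warning.
* Truth-evaluation state matching uses maximal emission correlation with a
  minimal-distance fallback when either emission row has range < 0.2
  (correlation is meaningless for the near-constant null state).
* Every source of randomness flows from an explicit integer seed; the
  permutation test, the EM fit and the generator are reproducible given
  their inputs and seed.

# Known limitations

* The Bernoulli HMM assumes conditional independence of marks given the
  state and a homogeneous chain along the genome; neither holds exactly in
  real chromatin.
* EM finds local optima; `init = "patterns"` removes most of the
  variability on data of this kind but is itself a heuristic.
* Gene bodies only — no promoter flanks, no sub-genic signature
  resolution.
* The signature class table (ACTIVATION/MIXED/REPRESSION split) is a
  convention; analyses that depend on class boundaries should state which
  table they used (outputs record it).
* The expression-window matched test can be infeasible on small pools with
  wide expression spread; the pipeline logs and skips rather than
  substituting an unmatched test.
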