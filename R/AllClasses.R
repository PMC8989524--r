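#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom Rcpp sourceCpp
#' @useDynLib chromsig, .registration = TRUE
NULL

## Region classes a base of the genome can belong to.
REGION_CLASSES <- c("AUTOSOME", "PAR", "SDR_FEMALE", "SDR_MALE")

## The five emission-state groups; NULL_GROUP is the mark-devoid background.
STATE_GROUPS   <- c("PERMISSIVE1", "PERMISSIVE2", "MIXED", "SILENT")
NULL_GROUP     <- "NULL"
ALL_GROUPS     <- c(STATE_GROUPS, NULL_GROUP)

## Signature classes at the gene level.
SIGNATURE_CLASSES <- c("ACTIVATION", "MIXED", "REPRESSION", "NULL")

## The six histone marks profiled, in canonical column order.
DEFAULT_MARKS <- c("H3K4me3", "H3K9ac", "H3K27ac", "H3K36me3",
                   "H3K79me2", "H4K20me3")
TSS_MARKS     <- c("H3K4me3", "H3K9ac", "H3K27ac")
GENEBODY_MARK <- "H3K36me3"
REPRESSIVE_MARKS <- c("H3K79me2", "H4K20me3")

#' GenomeLayout: chromosome sizes plus PAR/SDR region annotation
#'
#' Chromosome lengths together with a partition of every chromosome into
#' `AUTOSOME`, `PAR`, `SDR_FEMALE` and `SDR_MALE` regions.  The pseudoautosomal
#' region (PAR) and the non-recombining sex-determining regions (SDR) of a UV
#' sex chromosome are analysed separately from autosomes throughout the
#' package, so the layout is threaded through binning, coverage and the
#' permutation statistics.
#'
#' @slot seqlengths named integer vector of chromosome lengths (bp).
#' @slot regions [GenomicRanges::GRanges] with a `region_class` metadata
#'   column; jointly they tile every chromosome exactly once.
#' @export
setClass("GenomeLayout",
    representation(seqlengths = "integer", regions = "GRanges"))

setValidity("GenomeLayout", function(object) {
    sl <- object@seqlengths
    if (is.null(names(sl)) || any(!nzchar(names(sl))))
        return("chromosome lengths must be named")
    if (anyDuplicated(names(sl)))
        return("duplicate chromosome names")
    if (any(sl <= 0L))
        return("chromosome lengths must be positive")
    gr <- object@regions
    rc <- mcols(gr)$region_class
    if (is.null(rc) || !all(rc %in% REGION_CLASSES))
        return("regions need a region_class column limited to AUTOSOME/PAR/SDR_FEMALE/SDR_MALE")
    if (!all(as.character(seqnames(gr)) %in% names(sl)))
        return("region on unknown chromosome")
    bad <- end(gr) > sl[as.character(seqnames(gr))] | start(gr) < 1L
    if (any(bad))
        return(sprintf("region outside chromosome bounds: %s",
                       paste(regionLabel(gr[bad]), collapse = ", ")))
    ## PAR and SDR regions must not overlap one another
    special <- gr[rc != "AUTOSOME"]
    if (length(special) > 1L) {
        hits <- GenomicRanges::findOverlaps(special, drop.self = TRUE,
                                            drop.redundant = TRUE)
        if (length(hits) > 0L) {
            i <- S4Vectors::queryHits(hits)[1L]
            j <- S4Vectors::subjectHits(hits)[1L]
            return(sprintf("overlapping PAR/SDR regions: %s and %s",
                           regionLabel(special[i]), regionLabel(special[j])))
        }
    }
    ## exact partition: per chromosome, region widths must sum to the length
    w <- tapply(width(gr), as.character(seqnames(gr)), sum)
    cov <- GenomicRanges::reduce(gr)
    wc <- tapply(width(cov), as.character(seqnames(cov)), sum)
    for (chr in names(sl)) {
        tot <- if (chr %in% names(w)) w[[chr]] else 0L
        red <- if (chr %in% names(wc)) wc[[chr]] else 0L
        if (tot != sl[[chr]] || red != sl[[chr]])
            return(sprintf("regions of %s do not partition [0, %d)", chr, sl[[chr]]))
    }
    TRUE
})

regionLabel <- function(gr) {
    sprintf("%s:[%d,%d)", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' BinnedTrack: fixed-width binned signal for one mark and sample
#'
#' Per-chromosome vectors of non-negative values (read counts or coverage
#' ratios) at a fixed bin width, the unit the binarizer and the SES scaler
#' operate on.
#'
#' @slot binSize bin width in bp (default 200 throughout the package).
#' @slot values named list, one numeric vector per chromosome.
#' @slot mark mark name (e.g. "H3K4me3"); `""` for controls.
#' @slot sample free-text sample label (sex, replicate).
#' @slot seqlengths chromosome lengths the track was binned against.
#' @export
setClass("BinnedTrack",
    representation(binSize = "integer", values = "list", mark = "character",
                   sample = "character", seqlengths = "integer"))

setValidity("BinnedTrack", function(object) {
    if (object@binSize < 1L) return("binSize must be >= 1")
    sl <- object@seqlengths
    if (!identical(sort(names(object@values)), sort(names(sl))))
        return("values must have one vector per chromosome of the layout")
    for (chr in names(sl)) {
        v <- object@values[[chr]]
        nb <- nBins(sl[[chr]], object@binSize)
        if (length(v) != nb)
            return(sprintf("%s: expected %d bins, got %d", chr, nb, length(v)))
        if (any(!is.finite(v)) || any(v < 0))
            return(sprintf("%s: values must be finite and >= 0", chr))
    }
    TRUE
})

nBins <- function(len, binSize) as.integer(ceiling(len / binSize))

#' BinaryMatrix: bins x marks presence/absence observations
#'
#' The observation sequence of the hidden Markov model: one row per 200-bp
#' genomic bin, one column per histone mark, entries in \{0, 1\}.  Rows are
#' grouped by chromosome (`rowChrom`), each chromosome forming an independent
#' observation sequence.
#'
#' @slot binSize bin width in bp.
#' @slot marks ordered mark names (the fixed column order).
#' @slot data integer 0/1 matrix, rows = all bins of the layout in chromosome
#'   order.
#' @slot rowChrom chromosome of each row.
#' @slot rowBin 0-based bin index of each row within its chromosome.
#' @slot seqlengths chromosome lengths.
#' @slot sample sample label (typically the sex).
#' @export
setClass("BinaryMatrix",
    representation(binSize = "integer", marks = "character", data = "matrix",
                   rowChrom = "character", rowBin = "integer",
                   seqlengths = "integer", sample = "character"))

setValidity("BinaryMatrix", function(object) {
    d <- object@data
    if (!all(d %in% c(0L, 1L))) return("entries must be 0/1")
    if (ncol(d) != length(object@marks)) return("one column per mark required")
    if (anyDuplicated(object@marks)) return("duplicate mark names")
    exp_rows <- sum(nBins(object@seqlengths, object@binSize))
    if (nrow(d) != exp_rows)
        return(sprintf("row count %d != total bins %d of the layout",
                       nrow(d), exp_rows))
    if (length(object@rowChrom) != nrow(d) || length(object@rowBin) != nrow(d))
        return("rowChrom/rowBin must map every row")
    TRUE
})

#' BernoulliHMM: K-state hidden Markov model with Bernoulli emissions
#'
#' Each hidden state emits every mark independently with a state-specific
#' probability, so a state is a combinatorial chromatin pattern over the
#' profiled marks.  Fitted by Baum-Welch on pooled male + female observation
#' sequences (one joint model for both sexes).
#'
#' @slot K number of states.
#' @slot emission K x M matrix of per-state per-mark emission probabilities,
#'   clipped to `[1e-6, 1 - 1e-6]`.
#' @slot transition K x K row-stochastic transition matrix.
#' @slot initial length-K initial state distribution.
#' @slot marks mark names (column names of `emission`).
#' @slot metadata list: seed, iterations, logLik trace, convergence flag.
#' @export
setClass("BernoulliHMM",
    representation(K = "integer", emission = "matrix", transition = "matrix",
                   initial = "numeric", marks = "character",
                   metadata = "list"))

EMISSION_EPS <- 1e-6

setValidity("BernoulliHMM", function(object) {
    K <- object@K
    if (K < 1L) return("K must be >= 1")
    if (!identical(dim(object@emission), c(K, length(object@marks))))
        return("emission must be K x M")
    if (any(object@emission < EMISSION_EPS - 1e-12) ||
        any(object@emission > 1 - EMISSION_EPS + 1e-12))
        return("emission probabilities must lie in [1e-6, 1 - 1e-6]")
    if (!identical(dim(object@transition), c(K, K)))
        return("transition must be K x K")
    if (any(abs(rowSums(object@transition) - 1) > 1e-9))
        return("transition rows must sum to 1")
    if (length(object@initial) != K || abs(sum(object@initial) - 1) > 1e-9)
        return("initial distribution must be length K and sum to 1")
    ll <- object@metadata$logLik
    if (!is.null(ll) && length(ll) > 1L && any(diff(ll) < -1e-8))
        return("recorded log-likelihood trace must be non-decreasing")
    TRUE
})

#' Segmentation: decoded chromatin-state tiles
#'
#' Bin-aligned, sorted, non-overlapping tiles labelled `E1..EK` that jointly
#' cover every chromosome of the layout they were decoded against.
#'
#' @slot tiles [GenomicRanges::GRanges] with a `state` metadata column.
#' @slot binSize bin width in bp.
#' @slot sample sample label (sex).
#' @slot K number of states of the producing model.
#' @export
setClass("Segmentation",
    representation(tiles = "GRanges", binSize = "integer",
                   sample = "character", K = "integer"))

setValidity("Segmentation", function(object) {
    gr <- object@tiles
    st <- mcols(gr)$state
    if (is.null(st)) return("tiles need a state column")
    if (!all(grepl("^E[0-9]+$", st))) return("state labels must be E<k>")
    if (any(as.integer(sub("^E", "", st)) > object@K))
        return("state label beyond model K")
    if (any((start(gr) - 1L) %% object@binSize != 0L))
        return("tile starts must be bin-aligned")
    TRUE
})

#' GeneSignatureTable: per-gene chromatin signature assignment
#'
#' For one sex: the emission states overlapping each gene body, the derived
#' state-group set, the signature identifier `S1..S16` (S16 = the null
#' signature, genes overlapping nothing but the null state) and a signature
#' class.
#'
#' @slot table [S4Vectors::DataFrame] with columns `gene_id`, `states`
#'   (CharacterList), `groups` (CharacterList), `signature`, `class`.
#' @slot sample sample label (sex).
#' @export
setClass("GeneSignatureTable",
    representation(table = "DataFrame", sample = "character"))

setValidity("GeneSignatureTable", function(object) {
    tb <- object@table
    need <- c("gene_id", "states", "groups", "signature", "class")
    if (!all(need %in% colnames(tb)))
        return(sprintf("missing columns: %s",
                       paste(setdiff(need, colnames(tb)), collapse = ", ")))
    if (anyDuplicated(tb$gene_id)) return("duplicate gene_id")
    if (!all(tb$signature %in% paste0("S", 1:16)))
        return("signatures must be S1..S16")
    empty <- lengths(tb$groups) == 0L
    if (!identical(unname(empty), unname(tb$signature == "S16")))
        return("S16 must coincide exactly with an empty group set")
    TRUE
})

#' PermutationResult: covariate-matched subsampling permutation test result
#'
#' Observed Pearson chi-square statistic of a target gene set's signature
#' counts against pool proportions, the null distribution obtained by
#' repeatedly drawing matched subsamples from the pool, and the empirical
#' p-value `(b + 1) / (n_perm + 1)`.
#'
#' @slot observed observed chi-square statistic.
#' @slot nullDraws numeric vector of null statistics (length `nPerm`).
#' @slot pValue empirical p-value.
#' @slot matching one of `"NONE"`, `"TE_PREVALENCE"`, `"EXPRESSION_WINDOW"`.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @slot details list: category levels, target counts, pool proportions,
#'   per-stratum draw matrices for audit.
#' @export
setClass("PermutationResult",
    representation(observed = "numeric", nullDraws = "numeric",
                   pValue = "numeric", matching = "character",
                   nPerm = "integer", seed = "integer", details = "list"))

setValidity("PermutationResult", function(object) {
    if (!object@matching %in% c("NONE", "TE_PREVALENCE", "EXPRESSION_WINDOW"))
        return("unknown matching mode")
    if (object@pValue <= 0 || object@pValue > 1)
        return("empirical p must lie in (0, 1]")
    TRUE
})
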