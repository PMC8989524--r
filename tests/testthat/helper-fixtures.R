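## Shared fixtures and independent oracles, all built in code.

suppressWarnings(suppressMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
}))

tinyLayout <- function(len = 2000L, name = "chr1")
    makeGenomeLayout(stats::setNames(len, name))

sexLayout <- function()
    makeGenomeLayout(
        c(chrA = 2000L, sctg_sex = 1000L),
        data.frame(chromosome = "sctg_sex", start = c(0L, 600L),
                   end = c(600L, 900L),
                   region_class = c("PAR", "SDR_MALE")))

## GRanges of reads from 0-based starts
readsAt <- function(starts, chrom = "chr1", width = 50L)
    GRanges(chrom, IRanges(start = starts + 1L, width = width))

## GRanges of genes from 0-based half-open intervals
genesAt <- function(starts, ends, ids = sprintf("g%02d", seq_along(starts)),
                    chrom = "chr1") {
    gr <- GRanges(chrom, IRanges(starts + 1L, ends))
    mcols(gr)$gene_id <- ids
    mcols(gr)$region_class <- "AUTOSOME"
    mcols(gr)$te_overlap <- FALSE
    mcols(gr)$age_class <- "UNKNOWN"
    names(gr) <- ids
    gr
}

segFromTiles <- function(starts, ends, states, chrom = "chr1",
                         binSize = 200L, K = 12L) {
    makeSegmentation(GRanges(chrom, IRanges(starts + 1L, ends),
                             state = states),
                     binSize = binSize, K = K, merge = FALSE)
}

randomHMM <- function(K, M, seed) {
    withr::with_seed(seed, {
        E <- matrix(stats::runif(K * M, 0.05, 0.95), K, M,
                    dimnames = list(NULL, paste0("m", seq_len(M))))
        A <- matrix(stats::rgamma(K * K, 1), K, K)
        A <- A / rowSums(A)
        p <- stats::rgamma(K, 1)
        new("BernoulliHMM", K = as.integer(K),
            emission = pmin(pmax(E, 1e-6), 1 - 1e-6),
            transition = A, initial = p / sum(p),
            marks = paste0("m", seq_len(M)), metadata = list())
    })
}

## Exhaustive-path oracle: posteriors and log-likelihood by enumerating all
## K^T hidden paths of a short sequence.
enumPosterior <- function(model, X) {
    K <- nStates(model)
    T_ <- nrow(X)
    E <- emissionProbs(model)
    A <- transitionProbs(model)
    p0 <- initialProbs(model)
    emis <- function(k, t)
        prod(ifelse(X[t, ] == 1, E[k, ], 1 - E[k, ]))
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
    probs <- apply(paths, 1L, function(z) {
        p <- p0[z[1L]] * emis(z[1L], 1L)
        if (T_ > 1L) for (t in 2:T_)
            p <- p * A[z[t - 1L], z[t]] * emis(z[t], t)
        p
    })
    tot <- sum(probs)
    gamma <- matrix(0, T_, K)
    for (t in seq_len(T_)) for (k in seq_len(K))
        gamma[t, k] <- sum(probs[paths[, t] == k]) / tot
    list(gamma = gamma, loglik = log(tot))
}

## Brute-force signature oracle: nested loops over every gene-tile pair.
bruteForceSignatures <- function(seg, genes, map, minOverlap = 1L) {
    gr <- tiles(seg)
    tChr <- as.character(seqnames(gr)); tS <- start(gr); tE <- end(gr)
    tState <- mcols(gr)$state
    gChr <- as.character(seqnames(genes)); gS <- start(genes)
    gE <- end(genes)
    bits <- c(PERMISSIVE1 = 1L, PERMISSIVE2 = 2L, MIXED = 4L, SILENT = 8L)
    out <- character(length(genes))
    for (i in seq_along(genes)) {
        states <- character(0)
        for (j in seq_along(gr)) {
            if (gChr[i] != tChr[j]) next
            ov <- min(gE[i], tE[j]) - max(gS[i], tS[j]) + 1L
            if (ov >= minOverlap) states <- c(states, tState[j])
        }
        grps <- setdiff(unique(unname(map[unique(states)])), "NULL")
        out[i] <- if (length(grps) == 0L) "S16"
                  else paste0("S", sum(bits[grps]))
    }
    stats::setNames(out, mcols(genes)$gene_id)
}

## GeneSignatureTable realising the given signature labels (S1..S16), built
## through the real assignment path from representative state sets.
makePermGst <- function(sigs, sample = "") {
    ids <- names(sigs)
    if (is.null(ids)) ids <- sprintf("g%04d", seq_along(sigs))
    sets <- lapply(sigs, function(sg) {
        mask <- as.integer(sub("S", "", sg))
        if (mask == 16L) return("E12")
        c("E1", "E4", "E6", "E9")[which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)]
    })
    names(sets) <- ids
    assignSignatures(sets, defaultStateGroupMap(), sample = sample)
}

## Segmentation from one per-bin state vector on chr1.
binStatesToSegmentationForTest <- function(states, nbins, binSize = 200L) {
    r <- rle(states)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    segFromTiles((s - 1L) * binSize, e * binSize, r$values,
                 binSize = binSize)
}

## One shared default synthetic dataset + pipeline run for the end-to-end
## tests (generated once per session).
.e2e <- new.env(parent = emptyenv())
e2eRun <- function() {
    if (!is.null(.e2e$res)) return(.e2e)
    dataDir <- file.path(tempdir(), "chromsig-e2e-data")
    outDir <- file.path(tempdir(), "chromsig-e2e-out")
    .e2e$truth <- generateDataset(syntheticConfig(seed = 1), dataDir)
    .e2e$res <- suppressWarnings(runPipeline(
        runConfig(dataDir, outDir, nPerm = 2000L, maxIter = 150L,
                  seed = 1L)))
    .e2e$outDir <- outDir
    .e2e
}
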