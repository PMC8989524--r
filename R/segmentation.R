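#' Construct a Segmentation from state tiles
#'
#' @param tiles [GenomicRanges::GRanges] with a `state` metadata column
#'   (`E1..EK`).
#' @param binSize bin width in bp.
#' @param K number of model states (default: highest state label present).
#' @param sample sample label.
#' @param merge merge adjacent same-state tiles (default TRUE).
#' @return a [Segmentation-class].
#' @export
makeSegmentation <- function(tiles, binSize, K = NULL, sample = "",
                             merge = TRUE) {
    tiles <- sort(tiles, ignore.strand = TRUE)
    if (is.null(K))
        K <- max(as.integer(sub("^E", "", mcols(tiles)$state)))
    if (merge) tiles <- mergeStateTiles(tiles)
    new("Segmentation", tiles = tiles, binSize = as.integer(binSize),
        sample = sample, K = as.integer(K))
}

## Turn per-chromosome integer state vectors (one entry per bin) into a
## merged Segmentation.
binStatesToSegmentation <- function(statesByChrom, seqlengths, binSize, K,
                                    sample = "") {
    chr <- character(0); s1 <- integer(0); e1 <- integer(0); st <- character(0)
    for (cn in names(statesByChrom)) {
        r <- rle(statesByChrom[[cn]])
        endBin <- cumsum(r$lengths)
        startBin <- endBin - r$lengths + 1L
        chr <- c(chr, rep(cn, length(r$values)))
        s1 <- c(s1, (startBin - 1L) * binSize + 1L)
        e1 <- c(e1, pmin(endBin * binSize, seqlengths[[cn]]))
        st <- c(st, paste0("E", r$values))
    }
    makeSegmentation(GRanges(chr, IRanges(s1, e1), state = st),
                     binSize = binSize, K = K, sample = sample,
                     merge = FALSE)
}

#' Segmentation of the recorded true bin states of a synthetic dataset
#'
#' @param truth a truth bundle from [generateDataset()].
#' @param sex `"female"` or `"male"`.
#' @return a [Segmentation-class] of the true states.
#' @export
truthSegmentation <- function(truth, sex) {
    binStatesToSegmentation(truth$states[[sex]],
                            chromLengths(truth$layout),
                            truth$config$binSize, 12L, sample = sex)
}

mergeStateTiles <- function(gr) {
    if (length(gr) < 2L) return(gr)
    chr <- as.character(seqnames(gr))
    st <- mcols(gr)$state
    newRun <- c(TRUE, chr[-1L] != chr[-length(gr)] |
                      st[-1L] != st[-length(gr)] |
                      start(gr)[-1L] != end(gr)[-length(gr)] + 1L)
    grp <- cumsum(newRun)
    first <- !duplicated(grp)
    last <- !duplicated(grp, fromLast = TRUE)
    GRanges(chr[first],
            IRanges(start = start(gr)[first], end = end(gr)[last]),
            state = st[first])
}

#' Write a segmentation in the 4-column BED dialect
#'
#' Columns: chromosome, start, end (0-based half-open), state label `E<k>`.
#' Adjacent tiles with the same state are merged on write.  A header comment
#' records the bin size so the file round-trips.
#'
#' @param seg a [Segmentation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegmentation <- function(seg, path) {
    gr <- mergeStateTiles(tiles(seg))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#binSize=%d sample=%s K=%d", binSize(seg),
                       sampleLabel(seg), seg@K), con)
    writeLines(sprintf("%s\t%d\t%d\t%s", as.character(seqnames(gr)),
                       start(gr) - 1L, end(gr), mcols(gr)$state), con)
    invisible(path)
}

#' Read a segmentation written by [writeSegmentation()]
#'
#' @param path input path.
#' @param binSize bin width; taken from the header comment when `NULL`.
#' @return a [Segmentation-class].
#' @export
readSegmentation <- function(path, binSize = NULL) {
    lines <- readLines(path)
    header <- grep("^#", lines, value = TRUE)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    sample <- ""
    K <- NULL
    if (length(header) > 0L) {
        if (is.null(binSize)) {
            m <- regmatches(header[1L], regexec("binSize=([0-9]+)", header[1L]))[[1L]]
            if (length(m) == 2L) binSize <- as.integer(m[2L])
        }
        m <- regmatches(header[1L], regexec("sample=(\\S*)", header[1L]))[[1L]]
        if (length(m) == 2L) sample <- m[2L]
        m <- regmatches(header[1L], regexec("K=([0-9]+)", header[1L]))[[1L]]
        if (length(m) == 2L) K <- as.integer(m[2L])
    }
    if (is.null(binSize))
        stop("bin size neither given nor recorded in the file header")
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L)) stop("malformed segmentation line")
    chrom <- vapply(fields, `[[`, "", 1L)
    s0 <- as.integer(vapply(fields, `[[`, "", 2L))
    e0 <- as.integer(vapply(fields, `[[`, "", 3L))
    state <- vapply(fields, `[[`, "", 4L)
    bad <- !grepl("^E[0-9]+$", state)
    if (any(bad)) stop("unknown state label: ",
                       paste(unique(state[bad]), collapse = ", "))
    if (any(s0 %% binSize != 0L))
        stop("non-bin-aligned interval at line(s): ",
             paste(which(s0 %% binSize != 0L)[1:min(3, sum(s0 %% binSize != 0L))],
                   collapse = ", "))
    gr <- GRanges(chrom, IRanges(s0 + 1L, e0), state = state)
    makeSegmentation(gr, binSize = binSize, K = K, sample = sample,
                     merge = FALSE)
}
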