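#' Bin read intervals into a fixed-width track
#'
#' Each read interval increments the count of the bin containing its leftmost
#' (5') coordinate; strand is ignored.  The trailing partial bin of each
#' chromosome is included, so a chromosome of length L yields `ceiling(L /
#' binSize)` bins.
#'
#' @param intervals a [GenomicRanges::GRanges] of read intervals.
#' @param layout a [GenomeLayout-class].
#' @param binSize bin width in bp (default 200).
#' @param mark,sample labels stored on the track.
#' @return a [BinnedTrack-class].
#' @export
binSignal <- function(intervals, layout, binSize = 200L, mark = "",
                      sample = "") {
    binSize <- as.integer(binSize)
    sl <- chromLengths(layout)
    chr <- as.character(seqnames(intervals))
    unknown <- setdiff(unique(chr), names(sl))
    if (length(unknown) > 0L)
        stop("interval on unknown chromosome: ",
             paste(unknown, collapse = ", "))
    start0 <- start(intervals) - 1L
    values <- lapply(names(sl), function(cn) {
        nb <- nBins(sl[[cn]], binSize)
        s <- start0[chr == cn]
        if (length(s) == 0L) return(numeric(nb))
        as.numeric(tabulate(s %/% binSize + 1L, nbins = nb))
    })
    names(values) <- names(sl)
    new("BinnedTrack", binSize = binSize, values = values, mark = mark,
        sample = sample, seqlengths = sl)
}

#' Build a BinnedTrack directly from per-chromosome value vectors
#'
#' @param values named list of numeric vectors (one per chromosome).
#' @param layout a [GenomeLayout-class].
#' @param binSize bin width in bp.
#' @param mark,sample labels.
#' @return a [BinnedTrack-class].
#' @export
makeBinnedTrack <- function(values, layout, binSize = 200L, mark = "",
                            sample = "") {
    new("BinnedTrack", binSize = as.integer(binSize), values = values,
        mark = mark, sample = sample, seqlengths = chromLengths(layout))
}

trackVector <- function(track) unlist(track@values, use.names = FALSE)

sameGrid <- function(a, b) {
    identical(a@binSize, b@binSize) &&
        identical(a@seqlengths[order(names(a@seqlengths))],
                  b@seqlengths[order(names(b@seqlengths))])
}

#' Signal extraction scaling (SES) of an IP track against a control
#'
#' Orders bins by ascending IP signal, finds the rank at which the gap between
#' the cumulative control fraction and the cumulative IP fraction is maximal
#' (the background segment), and scales the control by the IP/control ratio
#' over that segment.  The returned ratio track is `IP / (scale_factor *
#' control)`, the background-normalised enrichment used for display tracks.
#'
#' @param ip,control [BinnedTrack-class] objects on the same layout and grid.
#' @param ratioCap value substituted for `x / 0` with `x > 0` (default 50);
#'   `0 / 0` bins yield 0.
#' @return list with elements `ratio` (a [BinnedTrack-class]) and
#'   `scale_factor`.
#' @export
sesNormalize <- function(ip, control, ratioCap = 50) {
    if (!sameGrid(ip, control))
        stop("IP and control tracks are on different layouts or bin sizes")
    x <- trackVector(ip)
    y <- trackVector(control)
    if (sum(y) <= 0) stop("all-zero control track")
    ord <- order(x)
    cumIP <- cumsum(x[ord]) / sum(x)
    cumC  <- cumsum(y[ord]) / sum(y)
    kstar <- which.max(cumC - cumIP)
    ipBg <- sum(x[ord][seq_len(kstar)])
    cBg  <- sum(y[ord][seq_len(kstar)])
    scale_factor <- if (cBg > 0) ipBg / cBg else sum(x) / sum(y)
    ratio <- lapply(names(ip@values), function(cn) {
        num <- ip@values[[cn]]
        den <- scale_factor * control@values[[cn]]
        r <- ifelse(den > 0, num / den, ifelse(num > 0, ratioCap, 0))
        pmin(r, ratioCap)
    })
    names(ratio) <- names(ip@values)
    list(ratio = new("BinnedTrack", binSize = ip@binSize, values = ratio,
                     mark = ip@mark, sample = ip@sample,
                     seqlengths = ip@seqlengths),
         scale_factor = scale_factor)
}

#' Binarize a binned IP track against a Poisson background
#'
#' Per bin, the expected background is `lambda = control * (total IP / total
#' control)` when a control track is supplied, else the global mean IP per
#' bin; `lambda` is floored at `lambdaMin` to avoid degenerate zero-background
#' calls.  A bin is called present (1) iff the Poisson upper tail `P(X >=
#' observed | lambda)` is `<= pThreshold`.
#'
#' @param ip a [BinnedTrack-class] of counts.
#' @param control optional [BinnedTrack-class] on the same grid.
#' @param pThreshold Poisson tail threshold in (0, 1); default 1e-4.
#' @param lambdaMin floor applied to the background rate; default 1.
#' @return named list of logical/integer vectors (one per chromosome), the
#'   single-mark binary column.
#' @export
binarizeTrack <- function(ip, control = NULL, pThreshold = 1e-4,
                          lambdaMin = 1) {
    if (pThreshold <= 0 || pThreshold >= 1)
        stop("pThreshold must lie in (0, 1)")
    x <- trackVector(ip)
    if (any(x < 0)) stop("negative counts in IP track")
    if (is.null(control)) {
        lam <- rep(mean(x), length(x))
    } else {
        if (!sameGrid(ip, control))
            stop("IP and control tracks are on different layouts or bin sizes")
        y <- trackVector(control)
        if (any(y < 0)) stop("negative counts in control track")
        tot <- sum(y)
        lam <- if (tot > 0) y * (sum(x) / tot) else rep(mean(x), length(x))
    }
    lam <- pmax(lam, lambdaMin)
    ## P(X >= x | lambda) = ppois(x - 1, lambda, lower.tail = FALSE)
    call <- as.integer(stats::ppois(x - 1, lam, lower.tail = FALSE) <= pThreshold)
    relist_track(call, ip)
}

relist_track <- function(v, track) {
    lens <- lengths(track@values)
    split(v, rep(seq_along(lens), lens)) |>
        stats::setNames(names(track@values))
}

#' Assemble single-mark binary columns into a BinaryMatrix
#'
#' @param columns named list (one entry per mark, in the desired column
#'   order) of per-chromosome binary-call lists as returned by
#'   [binarizeTrack()].
#' @param layout a [GenomeLayout-class].
#' @param binSize bin width in bp.
#' @param sample sample label (typically the sex).
#' @return a [BinaryMatrix-class].
#' @export
makeBinaryMatrix <- function(columns, layout, binSize = 200L, sample = "") {
    binSize <- as.integer(binSize)
    sl <- chromLengths(layout)
    markNames <- names(columns)
    if (is.null(markNames) || any(!nzchar(markNames)))
        stop("columns must be named by mark")
    chromOrder <- names(sl)
    dat <- do.call(cbind, lapply(columns, function(col) {
        unlist(col[chromOrder], use.names = FALSE)
    }))
    colnames(dat) <- markNames
    storage.mode(dat) <- "integer"
    nb <- nBins(sl, binSize)
    new("BinaryMatrix", binSize = binSize, marks = markNames, data = dat,
        rowChrom = rep(chromOrder, nb),
        rowBin = unlist(lapply(nb, function(n) seq_len(n) - 1L),
                        use.names = FALSE),
        seqlengths = sl, sample = sample)
}

#' Combine replicate binary matrices
#'
#' Replicate presence/absence calls for the same sample are combined per bin
#' by logical OR (default), AND, or by the caller pooling counts upstream.
#'
#' @param a,b [BinaryMatrix-class] objects with identical mark order and grid.
#' @param rule `"or"` or `"and"`.
#' @return a [BinaryMatrix-class].
#' @export
combineReplicates <- function(a, b, rule = c("or", "and")) {
    rule <- match.arg(rule)
    if (!identical(a@marks, b@marks)) stop("mark order differs between replicates")
    if (!identical(dim(a@data), dim(b@data))) stop("replicate grids differ")
    d <- if (rule == "or") pmax(a@data, b@data) else pmin(a@data, b@data)
    storage.mode(d) <- "integer"
    out <- a
    out@data <- d
    out
}
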