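#' Construct a GenomeLayout
#'
#' Builds a validated [GenomeLayout-class] from chromosome lengths and an
#' optional table of special regions (PAR / SDR).  Any span not covered by a
#' declared region is filled as `AUTOSOME`, so the layout always partitions
#' every chromosome.
#'
#' @param seqlengths named vector of chromosome lengths in bp.
#' @param regions optional data.frame with columns `chromosome`, `start`,
#'   `end`, `region_class`; coordinates are BED-style 0-based half-open.
#' @return a [GenomeLayout-class].
#' @examples
#' makeGenomeLayout(c(chr1 = 1000))
#' makeGenomeLayout(
#'   c(sctg_sex = 1000),
#'   data.frame(chromosome = "sctg_sex", start = c(0, 600), end = c(600, 900),
#'              region_class = c("PAR", "SDR_MALE")))
#' @export
makeGenomeLayout <- function(seqlengths, regions = NULL) {
    sl <- as.integer(round(seqlengths))
    names(sl) <- names(seqlengths)
    special <- GRanges()
    if (!is.null(regions) && nrow(regions) > 0L) {
        rc <- as.character(regions$region_class)
        if (!all(rc %in% REGION_CLASSES))
            stop("unknown region_class: ",
                 paste(setdiff(rc, REGION_CLASSES), collapse = ", "))
        special <- GRanges(regions$chromosome,
                           IRanges(start = regions$start + 1L,
                                   end = regions$end),
                           region_class = rc)
        bad <- !(as.character(seqnames(special)) %in% names(sl))
        if (any(bad))
            stop("region on unknown chromosome: ",
                 paste(unique(as.character(seqnames(special))[bad]),
                       collapse = ", "))
        off <- start(special) < 1L |
            end(special) > sl[as.character(seqnames(special))]
        if (any(off))
            stop("region outside chromosome bounds: ",
                 paste(regionLabel(special[off]), collapse = ", "))
        ov <- GenomicRanges::findOverlaps(special, drop.self = TRUE,
                                          drop.redundant = TRUE)
        if (length(ov) > 0L) {
            i <- S4Vectors::queryHits(ov)[1L]; j <- S4Vectors::subjectHits(ov)[1L]
            stop(sprintf("overlapping PAR/SDR regions: %s (%s) and %s (%s)",
                         regionLabel(special[i]), mcols(special)$region_class[i],
                         regionLabel(special[j]), mcols(special)$region_class[j]))
        }
    }
    genome <- GRanges(names(sl), IRanges(1L, sl))
    fill <- suppressWarnings(
        GenomicRanges::setdiff(genome, special, ignore.strand = TRUE))
    all <- GRanges(
        c(as.character(seqnames(special)), as.character(seqnames(fill))),
        IRanges(c(start(special), start(fill)),
                c(end(special), end(fill))),
        region_class = c(if (length(special)) mcols(special)$region_class,
                         rep("AUTOSOME", length(fill))))
    all <- sort(all, ignore.strand = TRUE)
    new("GenomeLayout", seqlengths = sl, regions = all)
}

#' Read a genome layout from a YAML config file
#'
#' The file has a `chromosomes` mapping (name -> length in bp) and an optional
#' `regions` list whose entries carry `chromosome`, `start`, `end` (0-based
#' half-open) and `class`.
#'
#' @param path path to the YAML layout file.
#' @return a [GenomeLayout-class].
#' @export
loadGenomeLayout <- function(path) {
    if (!file.exists(path)) stop("layout file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$chromosomes) || length(cfg$chromosomes) == 0L)
        stop("layout file declares no chromosomes")
    sl <- unlist(cfg$chromosomes)
    if (any(sl <= 0)) stop("chromosome lengths must be positive")
    regions <- NULL
    if (!is.null(cfg$regions) && length(cfg$regions) > 0L) {
        regions <- do.call(rbind, lapply(cfg$regions, function(r)
            data.frame(chromosome = r$chromosome,
                       start = as.numeric(r$start), end = as.numeric(r$end),
                       region_class = r$class)))
    }
    makeGenomeLayout(sl, regions)
}

#' Write a genome layout to a YAML config file
#'
#' @param layout a [GenomeLayout-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeLayout <- function(layout, path) {
    gr <- regions(layout)
    special <- gr[mcols(gr)$region_class != "AUTOSOME"]
    cfg <- list(
        chromosomes = as.list(chromLengths(layout)),
        regions = lapply(seq_along(special), function(i) list(
            chromosome = as.character(seqnames(special))[i],
            start = start(special)[i] - 1L,
            end = end(special)[i],
            class = mcols(special)$region_class[i])))
    if (length(cfg$regions) == 0L) cfg$regions <- NULL
    yaml::write_yaml(cfg, path)
    invisible(path)
}

#' Region class of genomic positions
#'
#' @param layout a [GenomeLayout-class].
#' @param chrom chromosome names.
#' @param pos 0-based positions.
#' @return character vector of region classes.
#' @export
regionClassAt <- function(layout, chrom, pos) {
    q <- GRanges(chrom, IRanges(pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(q, regions(layout), select = "first")
    if (anyNA(hits)) stop("position outside layout")
    mcols(regions(layout))$region_class[hits]
}
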