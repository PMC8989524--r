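#' Load gene models from GFF3 or BED
#'
#' Reads gene coordinates (GFF3 features of type `gene`, or BED4/BED6 lines),
#' assigns each gene the region class (autosome / PAR / SDR) of its midpoint
#' against the layout, and optionally attaches transposable-element overlap
#' flags and gene-age labels from side tables.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.  GFF3 is 1-based
#'   inclusive, BED 0-based half-open; both converted to the internal
#'   representation on read.
#' @param layout a [GenomeLayout-class]; genes must lie within its
#'   chromosomes.
#' @param tePath optional BED file of transposable-element insertions; a gene
#'   overlapping any interval by >= 1 bp gets `te_overlap = TRUE`.
#' @param agePath optional TSV with columns `gene_id`, `age_class`
#'   (`YOUNG`/`CONSERVED`); unlisted genes are `UNKNOWN`.
#' @return a [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `region_class`, `te_overlap`, `age_class`.
#' @export
loadGeneModels <- function(path, layout, tePath = NULL, agePath = NULL) {
    if (!file.exists(path)) stop("gene file not found: ", path)
    fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
    gr <- rtracklayer::import(path, format = fmt)
    if (fmt == "gff3") {
        gr <- gr[mcols(gr)$type == "gene"]
        ids <- mcols(gr)$ID
        if (is.null(ids) || anyNA(ids)) ids <- mcols(gr)$Name
    } else {
        ids <- mcols(gr)$name
    }
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
        stop("every gene needs an identifier (GFF3 ID attribute / BED name)")
    if (anyDuplicated(ids))
        stop("duplicate gene_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sl <- chromLengths(layout)
    chr <- as.character(seqnames(gr))
    if (!all(chr %in% names(sl)))
        stop("gene on unknown chromosome: ",
             paste(unique(chr[!chr %in% names(sl)]), collapse = ", "))
    if (any(start(gr) < 1L | end(gr) > sl[chr]))
        stop("gene extends beyond chromosome bounds")
    ## midpoint in 0-based coordinates: floor((start0 + end0) / 2)
    mid0 <- floor(((start(gr) - 1L) + end(gr)) / 2)
    genes <- GRanges(chr, IRanges(start(gr), end(gr)), strand = strand(gr))
    mcols(genes)$gene_id <- as.character(ids)
    mcols(genes)$region_class <- regionClassAt(layout, chr, mid0)
    mcols(genes)$te_overlap <- FALSE
    mcols(genes)$age_class <- "UNKNOWN"
    if (!is.null(tePath)) {
        te <- rtracklayer::import(tePath, format = "bed")
        mcols(genes)$te_overlap <-
            GenomicRanges::countOverlaps(genes, te, ignore.strand = TRUE) > 0L
    }
    if (!is.null(agePath)) {
        age <- utils::read.delim(agePath, stringsAsFactors = FALSE)
        if (!all(c("gene_id", "age_class") %in% colnames(age)))
            stop("age table needs gene_id and age_class columns")
        idx <- match(mcols(genes)$gene_id, age$gene_id)
        hit <- !is.na(idx)
        mcols(genes)$age_class[hit] <- age$age_class[idx[hit]]
    }
    names(genes) <- mcols(genes)$gene_id
    genes
}

#' Write gene models as GFF3
#'
#' @param genes GRanges as returned by [loadGeneModels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGFF3 <- function(genes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    strands <- as.character(strand(genes))
    strands[strands == "*"] <- "."
    writeLines(sprintf("%s\tchromsig\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(seqnames(genes)), start(genes),
                       end(genes), strands, mcols(genes)$gene_id), con)
    invisible(path)
}
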