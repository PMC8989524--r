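## Male/female comparisons: signature transitions, sex-specific mark
## domains, per-region mark coverage.

#' Male/female signature transition table
#'
#' Cross-tabulates each gene's signature in females (rows) against its
#' signature in males (columns); the diagonal holds genes whose signature is
#' stable between sexes.
#'
#' @param female,male [GeneSignatureTable-class] objects for the two sexes.
#' @param geneSubset gene ids to restrict to (default: genes present in both
#'   tables' intersection is required; all female-table genes by default).
#' @return list with `table` (16 x 16 count matrix), `n` (genes considered)
#'   and `fraction_changed` (`1 - diagonal / total`).
#' @export
signatureTransitions <- function(female, male, geneSubset = NULL) {
    ft <- signatureTable(female)
    mt <- signatureTable(male)
    if (is.null(geneSubset)) geneSubset <- ft$gene_id
    missF <- setdiff(geneSubset, ft$gene_id)
    missM <- setdiff(geneSubset, mt$gene_id)
    if (length(missF) + length(missM) > 0L)
        stop("gene(s) missing from the signature tables: ",
             paste(utils::head(c(missF, missM), 5L), collapse = ", "))
    fs <- ft$signature[match(geneSubset, ft$gene_id)]
    ms <- mt$signature[match(geneSubset, mt$gene_id)]
    lev <- paste0("S", 1:16)
    tab <- table(female = factor(fs, lev), male = factor(ms, lev))
    n <- length(geneSubset)
    list(table = unclass(tab), n = n,
         fraction_changed = 1 - sum(diag(tab)) / n)
}

#' Long-format edge list of a transition table
#'
#' A plain table (female signature, male signature, count) for external
#' chord-diagram plotting.
#'
#' @param transitions result of [signatureTransitions()].
#' @return data.frame with columns `from_female`, `to_male`, `count`
#'   (zero-count pairs dropped).
#' @export
transitionEdgeList <- function(transitions) {
    tab <- transitions$table
    idx <- which(tab > 0, arr.ind = TRUE)
    data.frame(from_female = rownames(tab)[idx[, 1L]],
               to_male = colnames(tab)[idx[, 2L]],
               count = tab[idx])[order(-tab[idx]), ]
}

#' Sex-specific mark domains and the genes carrying them
#'
#' A domain of one sex is sex-specific iff it overlaps no domain of the other
#' sex by >= 1 bp (intervals are merged first; end-to-start abutment does not
#' count as overlap).  A gene carries a sex-specific domain iff its body
#' overlaps one by >= 1 bp.
#'
#' @param domainsA,domainsB [GenomicRanges::GRanges] of mark domains for the
#'   two sexes (A-specific = absent from B, and vice versa).
#' @param genes gene models as returned by [loadGeneModels()].
#' @return list per sex (`a`, `b`): `domains` (the sex-specific intervals),
#'   `genes` (ids carrying one), `fraction` (of all genes).
#' @export
sexSpecificDomains <- function(domainsA, domainsB, genes) {
    tidy <- function(gr, label) {
        red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
        if (length(red) != length(gr))
            warning("unmerged or overlapping ", label,
                    " domains: auto-merged")
        red
    }
    a <- tidy(domainsA, "sex-A")
    b <- tidy(domainsB, "sex-B")
    specific <- function(x, y) {
        x[GenomicRanges::countOverlaps(x, y, ignore.strand = TRUE) == 0L]
    }
    aSpec <- specific(a, b)
    bSpec <- specific(b, a)
    carrier <- function(dom) {
        ids <- mcols(genes)$gene_id[
            GenomicRanges::countOverlaps(genes, dom,
                                         ignore.strand = TRUE) > 0L]
        list(genes = ids, fraction = length(ids) / length(genes))
    }
    ca <- carrier(aSpec); cb <- carrier(bSpec)
    list(a = list(domains = aSpec, genes = ca$genes, fraction = ca$fraction),
         b = list(domains = bSpec, genes = cb$genes, fraction = cb$fraction))
}

#' Mark coverage per genome region
#'
#' Fraction of each layout region (each chromosome's autosomal span, PAR and
#' SDRs separately) covered by the merged footprint of the supplied
#' intervals.
#'
#' @param enriched [GenomicRanges::GRanges] of enriched intervals for one
#'   mark and sex.
#' @param layout a [GenomeLayout-class].
#' @return data.frame: `chromosome`, `region_class`, `region_bp`,
#'   `covered_bp`, `coverage` (in `[0, 1]`).
#' @export
coverageByRegion <- function(enriched, layout) {
    reg <- regions(layout)
    if (any(width(reg) == 0L)) stop("zero-length region in layout")
    red <- GenomicRanges::reduce(enriched, ignore.strand = TRUE)
    key <- paste(as.character(seqnames(reg)), mcols(reg)$region_class)
    ov <- GenomicRanges::findOverlaps(reg, red)
    covered <- numeric(length(reg))
    if (length(ov) > 0L) {
        inter <- GenomicRanges::pintersect(
            reg[S4Vectors::queryHits(ov)], red[S4Vectors::subjectHits(ov)])
        covered <- as.numeric(tapply(width(inter),
                                     factor(S4Vectors::queryHits(ov),
                                            levels = seq_along(reg)),
                                     sum, default = 0))
        covered[is.na(covered)] <- 0
    }
    agg <- stats::aggregate(cbind(region_bp = width(reg),
                                  covered_bp = covered),
                            by = list(chromosome = as.character(seqnames(reg)),
                                      region_class = mcols(reg)$region_class),
                            FUN = sum)
    agg$coverage <- agg$covered_bp / agg$region_bp
    agg[order(agg$chromosome, agg$region_class), ]
}

#' Enriched-mark footprint from a binary matrix
#'
#' The merged genomic intervals of the bins called present for one mark, the
#' default notion of a mark "domain" when no external peak calls are
#' supplied.
#'
#' @param bm a [BinaryMatrix-class].
#' @param mark mark name.
#' @return [GenomicRanges::GRanges] of merged enriched intervals.
#' @export
markFootprint <- function(bm, mark) {
    if (!mark %in% bm@marks) stop("unknown mark: ", mark)
    on <- bm@data[, mark] == 1L
    if (!any(on)) return(GRanges())
    bs <- bm@binSize
    sl <- bm@seqlengths
    chr <- bm@rowChrom[on]
    bin <- bm@rowBin[on]
    gr <- GRanges(chr, IRanges(start = bin * bs + 1L,
                               end = pmin((bin + 1L) * bs, sl[chr])))
    GenomicRanges::reduce(gr, ignore.strand = TRUE)
}
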