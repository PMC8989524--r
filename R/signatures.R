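## Gene-level chromatin signatures: states -> five groups -> 16 signatures.
##
## A gene's signature is the set of non-null state groups overlapping its
## body, encoded by a bitmask (PERMISSIVE1 = bit 0, PERMISSIVE2 = bit 1,
## MIXED = bit 2, SILENT = bit 3): subset mask k in 1..15 -> S_k, the empty
## set -> S16 (the null signature: a gene overlapping no state outside the
## null group).

GROUP_BITS <- c(PERMISSIVE1 = 1L, PERMISSIVE2 = 2L, MIXED = 4L, SILENT = 8L)

#' Default emission-state to group map for a 12-state model
#'
#' States E1-E3 carry the TSS-proximal activation marks (group PERMISSIVE1),
#' E4-E5 the gene-body mark H3K36me3 (PERMISSIVE2), E6-E8 mix activation- and
#' repression-associated marks (MIXED), E9-E11 carry the repressive marks
#' (SILENT) and E12 is devoid of assayed marks (NULL).
#'
#' @param K number of states (only the 12-state default layout is built in).
#' @return named character vector, state label -> group.
#' @export
defaultStateGroupMap <- function(K = 12L) {
    if (K != 12L)
        stop("a built-in map exists only for K = 12; supply your own map")
    stats::setNames(c(rep("PERMISSIVE1", 3L), rep("PERMISSIVE2", 2L),
                      rep("MIXED", 3L), rep("SILENT", 3L), NULL_GROUP),
                    paste0("E", 1:12))
}

#' Read / write a state-group map as 2-column TSV
#'
#' @param path file path.
#' @return named character vector (read); `path` invisibly (write).
#' @export
readStateGroupMap <- function(path) {
    tb <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    map <- stats::setNames(tb[[2L]], tb[[1L]])
    if (!all(map %in% ALL_GROUPS))
        stop("unknown group in map: ",
             paste(setdiff(map, ALL_GROUPS), collapse = ", "))
    if (!any(map == NULL_GROUP))
        stop("state-group map must contain at least one NULL state")
    map
}

#' @rdname readStateGroupMap
#' @param map named character vector, state -> group.
#' @export
writeStateGroupMap <- function(map, path) {
    utils::write.table(data.frame(state = names(map), group = unname(map)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Classify fitted HMM states into the five groups from their emissions
#'
#' States of a refit model carry no intrinsic ordering, so group membership
#' is read off the emission profile: a state is NULL when every mark is below
#' `cutoff`; SILENT when a repressive mark is on and all activation marks are
#' off; MIXED when repressive and activation marks are both on; PERMISSIVE1
#' when a TSS mark is on (repressives off); PERMISSIVE2 when only the
#' gene-body mark is on.  If no state classifies as NULL, the state with the
#' smallest maximum emission is forced NULL so the map always has a null
#' state.
#'
#' @param model a [BernoulliHMM-class].
#' @param tssMarks,gbMark,repMarks mark names by functional role.
#' @param cutoff emission probability above which a mark counts as present.
#' @return named character vector, state label -> group.
#' @export
inferStateGroups <- function(model, tssMarks = TSS_MARKS,
                             gbMark = GENEBODY_MARK,
                             repMarks = REPRESSIVE_MARKS, cutoff = 0.5) {
    E <- emissionProbs(model)
    mk <- marks(model)
    colnames(E) <- mk
    hi <- function(cols) {
        cols <- intersect(cols, mk)
        if (length(cols) == 0L) return(rep(FALSE, nrow(E)))
        apply(E[, cols, drop = FALSE] >= cutoff, 1L, any)
    }
    tss <- hi(tssMarks); gb <- hi(gbMark); rep_ <- hi(repMarks)
    grp <- ifelse(!tss & !gb & !rep_, NULL_GROUP,
           ifelse(rep_ & (tss | gb), "MIXED",
           ifelse(rep_, "SILENT",
           ifelse(tss, "PERMISSIVE1", "PERMISSIVE2"))))
    if (!any(grp == NULL_GROUP))
        grp[which.min(apply(E, 1L, max))] <- NULL_GROUP
    stats::setNames(grp, paste0("E", seq_len(nrow(E))))
}

#' Intersect segmentation states with gene bodies
#'
#' A state is recorded for a gene iff some tile of that state overlaps the
#' gene body by at least `minOverlap` bp; strand is ignored.
#'
#' @param seg a [Segmentation-class] covering the genome.
#' @param genes gene models as returned by [loadGeneModels()].
#' @param minOverlap minimum overlap in bp (default 1).
#' @return named list, gene_id -> character vector of overlapping states.
#' @export
intersectStatesWithGenes <- function(seg, genes, minOverlap = 1L) {
    gr <- tiles(seg)
    missing <- setdiff(unique(as.character(seqnames(genes))),
                       unique(as.character(seqnames(gr))))
    if (length(missing) > 0L)
        stop("gene(s) on chromosome(s) absent from the segmentation: ",
             paste(missing, collapse = ", "))
    hits <- GenomicRanges::findOverlaps(genes, gr,
                                        minoverlap = as.integer(minOverlap),
                                        ignore.strand = TRUE)
    st <- mcols(gr)$state[S4Vectors::subjectHits(hits)]
    ids <- mcols(genes)$gene_id
    out <- lapply(split(st, factor(ids[S4Vectors::queryHits(hits)],
                                   levels = ids)),
                  function(s) sort(unique(s)))
    names(out) <- ids
    out
}

#' Map a set of state groups to its signature identifier
#'
#' @param groups character vector of non-null groups (may be empty).
#' @return `"S1".."S16"`.
#' @export
groupSetSignature <- function(groups) {
    groups <- setdiff(groups, NULL_GROUP)
    if (length(groups) == 0L) return("S16")
    paste0("S", sum(GROUP_BITS[unique(groups)]))
}

#' Signature class of each signature identifier
#'
#' Default rule: subsets containing only permissive groups are ACTIVATION;
#' subsets mixing a permissive group with MIXED or SILENT content are MIXED;
#' subsets without any permissive group are REPRESSION; the empty set (S16)
#' is NULL.
#'
#' @return named character vector, `S1..S16` -> class.
#' @export
defaultSignatureClassTable <- function() {
    cls <- vapply(1:15, function(mask) {
        permissive <- bitwAnd(mask, 3L) != 0L
        heavy <- bitwAnd(mask, 12L) != 0L
        if (permissive && !heavy) "ACTIVATION"
        else if (permissive) "MIXED"
        else "REPRESSION"
    }, "")
    stats::setNames(c(cls, "NULL"), paste0("S", 1:16))
}

#' Assign chromatin signatures to genes
#'
#' Derives each gene's group set from its overlapping states (the NULL group
#' is dropped whenever any other group is present), maps the set to `S1..S16`
#' and attaches a signature class.  A gene overlapping nothing but null-group
#' states gets the null signature S16.
#'
#' @param stateSets named list, gene_id -> overlapping states, as returned by
#'   [intersectStatesWithGenes()].  Genes with no recorded states (empty
#'   vector) are treated as null-signature genes.
#' @param map named character vector, state -> group (e.g.
#'   [defaultStateGroupMap()] or [inferStateGroups()]).
#' @param classTable named character vector `S1..S16` -> class; default
#'   [defaultSignatureClassTable()].
#' @param idTable optional custom bijection from group subsets to signature
#'   ids: a named character vector keyed by the `+`-joined sorted group names
#'   (`""` for the empty set), e.g. `c("PERMISSIVE1+SILENT" = "S9", ...)`.
#'   By default the canonical bitmask order is used (see
#'   [groupSetSignature()]).
#' @param sample sample label (sex).
#' @return a [GeneSignatureTable-class].
#' @export
assignSignatures <- function(stateSets, map,
                             classTable = defaultSignatureClassTable(),
                             idTable = NULL, sample = "") {
    allStates <- unique(unlist(stateSets, use.names = FALSE))
    missing <- setdiff(allStates, names(map))
    if (length(missing) > 0L)
        stop("state(s) missing from the group map: ",
             paste(missing, collapse = ", "))
    groups <- lapply(stateSets, function(s)
        setdiff(sort(unique(unname(map[s]))), NULL_GROUP))
    sig <- if (is.null(idTable)) {
        vapply(groups, groupSetSignature, "")
    } else {
        keys <- vapply(groups, function(g) paste(sort(g), collapse = "+"), "")
        idx <- match(keys, names(idTable))  # match() also finds the "" key
        if (anyNA(idx))
            stop("group subset missing from idTable: ",
                 paste(unique(keys[is.na(idx)]), collapse = "; "))
        unname(idTable[idx])
    }
    tb <- DataFrame(gene_id = names(stateSets),
                    states = IRanges::CharacterList(stateSets),
                    groups = IRanges::CharacterList(groups),
                    signature = unname(sig),
                    class = unname(classTable[sig]))
    new("GeneSignatureTable", table = tb, sample = sample)
}

#' Signature proportions over a gene subset
#'
#' @param gst a [GeneSignatureTable-class].
#' @param geneSubset gene ids to restrict to (default: all genes).
#' @return data.frame with 16 rows: `signature`, `count`, `proportion`
#'   (proportions sum to 1).
#' @export
signatureProportions <- function(gst, geneSubset = NULL) {
    tb <- signatureTable(gst)
    if (!is.null(geneSubset)) {
        missing <- setdiff(geneSubset, tb$gene_id)
        if (length(missing) > 0L)
            stop("subset gene(s) absent from the table: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        tb <- tb[tb$gene_id %in% geneSubset, ]
    }
    if (nrow(tb) == 0L) stop("empty gene subset")
    counts <- table(factor(tb$signature, levels = paste0("S", 1:16)))
    data.frame(signature = paste0("S", 1:16),
               count = as.integer(counts),
               proportion = as.numeric(counts) / nrow(tb))
}

#' Signature counts of a gene subset as a named vector
#'
#' @param gst a [GeneSignatureTable-class].
#' @param geneSubset gene ids.
#' @return named integer vector over `S1..S16`.
#' @export
signatureCounts <- function(gst, geneSubset = NULL) {
    pr <- signatureProportions(gst, geneSubset)
    stats::setNames(pr$count, pr$signature)
}
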