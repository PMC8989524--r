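## Expression integration: TPM, expressed calls, tissue-specificity tau and
## sex-bias labels.

#' Compute transcripts per million from counts and gene lengths
#'
#' `rate = count / length` per gene; `TPM = 1e6 * rate / sum(rate)` per
#' sample, so every sample's TPM column sums to one million.
#'
#' @param counts genes x samples matrix of non-negative read counts
#'   (rownames = gene ids).
#' @param lengths per-gene lengths in bp (> 0), aligned with the rows.
#' @return genes x samples TPM matrix.
#' @export
computeTPM <- function(counts, lengths) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be >= 0")
    if (length(lengths) != nrow(counts))
        stop("one length per gene required")
    if (any(lengths <= 0)) stop("gene lengths must be > 0")
    rate <- counts / lengths
    tot <- colSums(rate)
    zero <- tot == 0
    if (any(zero)) {
        warning("all-zero sample(s): ",
                paste(colnames(counts)[zero], collapse = ", "))
        tot[zero] <- 1
    }
    sweep(rate, 2L, tot, "/") * 1e6
}

#' Call expressed genes by the per-sample fifth-percentile rule
#'
#' Per sample, the threshold is the 5th percentile of that sample's TPM
#' values (linear-interpolation percentile); a gene is expressed overall iff
#' its TPM reaches the threshold in at least one sample (`rule = "any"`) or
#' in every sample (`rule = "all"`).
#'
#' @param tpm genes x samples TPM matrix.
#' @param rule `"any"` (default) or `"all"`.
#' @param percentile percentile defining the threshold (default 0.05).
#' @return named logical vector of expressed flags.
#' @export
callExpressed <- function(tpm, rule = c("any", "all"), percentile = 0.05) {
    rule <- match.arg(rule)
    tpm <- as.matrix(tpm)
    if (nrow(tpm) == 0L) stop("empty expression table")
    if (nrow(tpm) < 20L)
        warning("fewer than 20 genes: the percentile threshold is degenerate")
    thr <- apply(tpm, 2L, stats::quantile, probs = percentile, names = FALSE)
    pass <- sweep(tpm, 2L, thr, ">=")
    flags <- if (rule == "any") rowSums(pass) > 0L else rowSums(pass) == ncol(tpm)
    stats::setNames(flags, rownames(tpm))
}

#' Tissue-specificity index tau and expression-breadth categories
#'
#' With `xhat_i = x_i / max_i(x_i)`, `tau = sum(1 - xhat_i) / (N - 1)` over N
#' conditions: 0 for uniform expression, 1 for single-condition expression.
#' Breadth: HOUSEKEEPING iff `tau < 0.25`, NARROW iff `tau > 0.75`, else
#' INTERMEDIATE (strict inequalities).  All-zero profiles give `NA` tau and
#' breadth.
#'
#' @param profile genes x conditions matrix of non-negative expression
#'   values.
#' @return data.frame with columns `gene_id`, `tau`, `breadth`.
#' @export
computeTau <- function(profile) {
    profile <- as.matrix(profile)
    if (ncol(profile) < 2L) stop("tau needs at least 2 conditions")
    if (any(profile < 0)) stop("expression values must be >= 0")
    mx <- apply(profile, 1L, max)
    tau <- ifelse(mx > 0,
                  rowSums(1 - profile / ifelse(mx > 0, mx, 1)) /
                      (ncol(profile) - 1L),
                  NA_real_)
    breadth <- ifelse(is.na(tau), NA_character_,
               ifelse(tau < 0.25, "HOUSEKEEPING",
               ifelse(tau > 0.75, "NARROW", "INTERMEDIATE")))
    data.frame(gene_id = rownames(profile) %||% as.character(seq_len(nrow(profile))),
               tau = unname(tau), breadth = unname(breadth))
}

#' Call sex-biased genes from a differential-expression table
#'
#' A gene is MALE_BIASED iff `log2FC >= 1` (male over female), `FDR < 0.05`
#' and mean male TPM `> 1`; FEMALE_BIASED symmetrically; otherwise UNBIASED.
#' Genes absent from the DE table are UNBIASED.
#'
#' @param deTable data.frame with columns `gene_id`, `log2FC` (male/female
#'   orientation), `padj`.
#' @param tpm genes x samples TPM matrix.
#' @param sex character vector labelling each TPM column `"male"` or
#'   `"female"`.
#' @param log2fcMin minimum |log2 fold change| (default 1, i.e. 2-fold).
#' @param fdrMax FDR threshold (default 0.05).
#' @param tpmMin required expression in the favoured sex (default 1,
#'   strict >).
#' @return data.frame with columns `gene_id`, `log2FC`, `padj`, `bias`.
#' @export
callSexBias <- function(deTable, tpm, sex, log2fcMin = 1, fdrMax = 0.05,
                        tpmMin = 1) {
    if (any(deTable$padj < 0 | deTable$padj > 1, na.rm = TRUE))
        stop("adjusted p-values must lie in [0, 1]")
    tpm <- as.matrix(tpm)
    if (length(sex) != ncol(tpm)) stop("one sex label per TPM column required")
    maleMean <- rowMeans(tpm[, sex == "male", drop = FALSE])
    femaleMean <- rowMeans(tpm[, sex == "female", drop = FALSE])
    ids <- rownames(tpm)
    idx <- match(ids, deTable$gene_id)
    l2fc <- ifelse(is.na(idx), NA_real_, deTable$log2FC[idx])
    padj <- ifelse(is.na(idx), NA_real_, deTable$padj[idx])
    bias <- rep("UNBIASED", length(ids))
    ok <- !is.na(l2fc) & !is.na(padj) & padj < fdrMax
    bias[ok & l2fc >= log2fcMin & maleMean > tpmMin] <- "MALE_BIASED"
    bias[ok & l2fc <= -log2fcMin & femaleMean > tpmMin] <- "FEMALE_BIASED"
    data.frame(gene_id = ids, log2FC = l2fc, padj = padj, bias = bias)
}
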