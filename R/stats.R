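## Chi-square proportion statistics, covariate-matched subsampling
## permutation tests, signature x location expression models, FDR.

#' Pearson chi-square statistic of counts against expected proportions
#'
#' `sum((O_c - E_c)^2 / E_c)` with `E_c = N * p_c`.  Categories with expected
#' proportion 0 and observed count 0 are dropped; an observed count in a
#' category with expected 0 makes the statistic infinite (flagged via the
#' `"degenerate"` attribute).
#'
#' @param observed named non-negative counts per category.
#' @param expected expected proportions per category (same names; sums to 1).
#' @return the statistic (possibly `Inf`).
#' @export
chiSquareStat <- function(observed, expected) {
    if (any(observed < 0)) stop("negative counts")
    if (!identical(sort(names(observed)), sort(names(expected))))
        stop("observed and expected must share a category set")
    expected <- expected[names(observed)]
    if (abs(sum(expected) - 1) > 1e-8)
        stop("expected proportions must sum to 1")
    keep <- !(expected == 0 & observed == 0)
    O <- observed[keep]; p <- expected[keep]
    if (any(p == 0)) {
        out <- Inf
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    E <- sum(O) * p
    sum((O - E)^2 / E)
}

## Vectorised multivariate hypergeometric sampler: nPerm draws of size k
## (scalar or per-draw vector) from category counts m; returns nPerm x C.
rMultiHyper <- function(nPerm, m, k) {
    C <- length(m)
    out <- matrix(0L, nPerm, C)
    remK <- rep_len(as.integer(k), nPerm)
    rem <- sum(m)
    if (C == 1L) { out[, 1L] <- remK; return(out) }
    for (cc in seq_len(C - 1L)) {
        rem <- rem - m[cc]
        x <- stats::rhyper(nPerm, m[cc], rem, remK)
        out[, cc] <- x
        remK <- remK - x
    }
    out[, C] <- remK
    out
}

#' Covariate-matched subsampling permutation test on signature proportions
#'
#' Compares a target gene set's chromatin-signature composition against a
#' pool (e.g. PAR genes against autosomal genes).  The observed statistic is
#' the Pearson chi-square of the target's signature counts against the
#' pool's signature proportions; the null distribution is obtained by
#' repeatedly drawing `|target|` genes from the pool without replacement
#' (optionally matched on a covariate) and recomputing the same statistic.
#' The empirical p-value is `(b + 1) / (n_perm + 1)` with `b` the number of
#' null draws at or above the observed statistic.
#'
#' Matching modes: `"TE_PREVALENCE"` stratifies the pool by
#' transposable-element overlap and forces every draw to contain exactly the
#' target's number of TE-overlapping and TE-free genes; `"EXPRESSION_WINDOW"`
#' restricts the pool to genes whose expression lies within `window` (default
#' 25%) of the target median before drawing.
#'
#' Because the statistic depends on a draw only through its per-signature
#' counts, null draws are sampled as (stratified) multivariate hypergeometric
#' category counts, which is exactly equivalent in distribution to sampling
#' gene indices without replacement.
#'
#' @param targetGenes,poolGenes disjoint gene-id vectors.
#' @param signatures a [GeneSignatureTable-class] covering both sets.
#' @param nPerm number of permutations (default 100000).
#' @param matching `"NONE"`, `"TE_PREVALENCE"` or `"EXPRESSION_WINDOW"`.
#' @param teFlags named logical vector (gene -> TE overlap), required for TE
#'   matching.
#' @param expression named numeric vector (gene -> mean expression),
#'   required for expression matching.
#' @param window half-width of the expression window as a fraction of the
#'   target median (default 0.25).
#' @param seed RNG seed.
#' @return a [PermutationResult-class].
#' @export
matchedPermutationTest <- function(targetGenes, poolGenes, signatures,
                                   nPerm = 100000L,
                                   matching = c("NONE", "TE_PREVALENCE",
                                                "EXPRESSION_WINDOW"),
                                   teFlags = NULL, expression = NULL,
                                   window = 0.25, seed = 1L) {
    matching <- match.arg(matching)
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (length(intersect(targetGenes, poolGenes)) > 0L)
        stop("target and pool gene sets must be disjoint")
    tb <- signatureTable(signatures)
    sig <- stats::setNames(tb$signature, tb$gene_id)
    missing <- setdiff(c(targetGenes, poolGenes), names(sig))
    if (length(missing) > 0L)
        stop("gene(s) without signatures: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    targetSig <- sig[targetGenes]
    poolSig <- sig[poolGenes]
    lev <- paste0("S", 1:16)
    lev <- lev[lev %in% union(targetSig, poolSig)]
    targetCounts <- table(factor(targetSig, lev))
    poolCounts <- table(factor(poolSig, lev))
    poolProp <- as.numeric(poolCounts) / length(poolGenes)
    names(poolProp) <- lev
    observed <- chiSquareStat(stats::setNames(as.numeric(targetCounts), lev),
                              poolProp)

    ## build sampling strata over the (matched) pool
    drawPool <- poolGenes
    if (matching == "EXPRESSION_WINDOW") {
        if (is.null(expression)) stop("expression matching needs expression values")
        med <- stats::median(expression[targetGenes])
        inWin <- expression[poolGenes] >= (1 - window) * med &
                 expression[poolGenes] <= (1 + window) * med
        drawPool <- poolGenes[!is.na(inWin) & inWin]
        if (length(drawPool) < length(targetGenes))
            stop(sprintf(paste0("expression matching infeasible: %d pool ",
                                "genes within the window, %d needed"),
                         length(drawPool), length(targetGenes)))
        strata <- list(list(pool = drawPool, n = length(targetGenes)))
    } else if (matching == "TE_PREVALENCE") {
        if (is.null(teFlags)) stop("TE matching needs TE-overlap flags")
        nTeTarget <- sum(teFlags[targetGenes])
        nFreeTarget <- length(targetGenes) - nTeTarget
        tePool <- poolGenes[teFlags[poolGenes]]
        freePool <- poolGenes[!teFlags[poolGenes]]
        if (length(tePool) < nTeTarget || length(freePool) < nFreeTarget)
            stop(sprintf(paste0("TE matching infeasible: need %d TE / %d ",
                                "TE-free pool genes, have %d / %d"),
                         nTeTarget, nFreeTarget, length(tePool),
                         length(freePool)))
        strata <- list(list(pool = tePool, n = nTeTarget),
                       list(pool = freePool, n = nFreeTarget))
        strata <- strata[vapply(strata, function(s) s$n > 0L, TRUE)]
    } else {
        strata <- list(list(pool = poolGenes, n = length(targetGenes)))
    }

    drawsByStratum <- withSeed(seed, lapply(strata, function(s) {
        m <- as.integer(table(factor(sig[s$pool], lev)))
        rMultiHyper(as.integer(nPerm), m, s$n)
    }))
    counts <- Reduce(`+`, drawsByStratum)
    E <- length(targetGenes) * poolProp
    keep <- E > 0
    nullStats <- as.numeric(
        (counts[, keep, drop = FALSE] -
             matrix(E[keep], nPerm, sum(keep), byrow = TRUE))^2 %*%
            (1 / E[keep]))
    b <- sum(nullStats >= as.numeric(observed))
    new("PermutationResult",
        observed = as.numeric(observed), nullDraws = nullStats,
        pValue = (b + 1) / (nPerm + 1), matching = matching,
        nPerm = as.integer(nPerm), seed = as.integer(seed),
        details = list(levels = lev,
                       target_counts = stats::setNames(as.integer(targetCounts), lev),
                       pool_proportions = poolProp,
                       strata_sizes = vapply(strata, function(s) s$n, 0L),
                       strata_draws = drawsByStratum,
                       degenerate = isTRUE(attr(observed, "degenerate"))))
}

#' Linear model of expression on chromatin signature and genomic location
#'
#' Ordinary least squares of `log2(TPM + 1)` on signature indicators (S1 as
#' the reference level), a location indicator (autosome vs PAR) and their
#' interaction.  Signature levels with fewer than two genes are dropped with
#' a warning; coefficients that the design cannot estimate (e.g. a signature
#' occurring only on the PAR) are reported as inestimable rather than
#' silently dropped.
#'
#' @param expr named numeric vector of `log2(TPM + 1)` values.
#' @param signature named character vector (gene -> signature `S1..S16`).
#' @param location named character vector (gene -> `"AUTOSOME"` or `"PAR"`).
#' @return list with `coefficients` (data.frame: `term`, `estimate`,
#'   `std_error`, `p_value`, `estimable`) and `fit` (the `lm` object).
#' @export
signatureExpressionModel <- function(expr, signature, location) {
    ids <- names(expr)
    df <- data.frame(expr = as.numeric(expr),
                     signature = as.character(signature[ids]),
                     location = as.character(location[ids]))
    cnt <- table(df$signature)
    drop <- names(cnt)[cnt < 2L]
    if (length(drop) > 0L) {
        warning("dropping signature level(s) with < 2 genes: ",
                paste(drop, collapse = ", "))
        df <- df[!df$signature %in% drop, ]
    }
    levs <- unique(df$signature)
    if (length(levs) < 2L) stop("need at least 2 signature levels")
    ref <- if ("S1" %in% levs) "S1" else sort(levs)[1L]
    df$signature <- stats::relevel(factor(df$signature), ref = ref)
    df$location <- factor(df$location)
    form <- if (nlevels(df$location) > 1L) expr ~ signature * location
            else expr ~ signature
    fit <- stats::lm(form, data = df)
    cf <- coef(fit)
    sm <- summary(fit)$coefficients
    out <- data.frame(term = names(cf),
                      estimate = unname(cf),
                      std_error = NA_real_, p_value = NA_real_,
                      estimable = !is.na(cf))
    hit <- match(rownames(sm), out$term)
    out$std_error[hit] <- sm[, "Std. Error"]
    out$p_value[hit] <- sm[, "Pr(>|t|)"]
    list(coefficients = out, fit = fit)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Validates the inputs and delegates to the standard step-up procedure with
#' monotonicity enforcement.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in `[0, 1]`.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Percentage of segregating sites from printed counts
#'
#' Share of valid sites that segregate between two strains, rounded to the
#' reporting precision; used to verify that near-isogenic lines differ only
#' at the sex-determining region.
#'
#' @param segregating number of sites segregating between the strains.
#' @param valid number of valid sites assessed.
#' @param digits decimal places of the reported percentage (default 3).
#' @return the rounded percentage.
#' @export
percentSegregating <- function(segregating, valid, digits = 3L) {
    if (valid <= 0) stop("valid site count must be positive")
    round(100 * segregating / valid, digits)
}
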