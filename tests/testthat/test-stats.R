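test_that("the chi-square statistic matches hand computation and flags degeneracy", {
    expect_equal(chiSquareStat(c(a = 25, b = 75),
                               c(a = 0.25, b = 0.75)), 0)
    ## observed (10, 0) against (0.5, 0.5): (10-5)^2/5 + (0-5)^2/5 = 10
    expect_equal(chiSquareStat(c(a = 10, b = 0), c(a = 0.5, b = 0.5)), 10)
    ## invariant under category relabelling
    expect_equal(chiSquareStat(c(x = 3, y = 9), c(x = 0.3, y = 0.7)),
                 chiSquareStat(c(y = 9, x = 3), c(y = 0.7, x = 0.3)))
    ## expected 0 with observed 0 drops; expected 0 with observed > 0 is Inf
    expect_equal(chiSquareStat(c(a = 10, b = 0), c(a = 1, b = 0)), 0)
    deg <- chiSquareStat(c(a = 8, b = 2), c(a = 1, b = 0))
    expect_identical(unname(as.numeric(deg)), Inf)
    expect_true(attr(deg, "degenerate"))
    expect_error(chiSquareStat(c(a = -1, b = 1), c(a = 0.5, b = 0.5)),
                 "negative")
})

permFixture <- function(nPool = 400, seed = 123) {
    withr::with_seed(seed, {
        sigs <- sample(paste0("S", c(1, 3, 7, 13, 16)), nPool + 40,
                       replace = TRUE, prob = c(0.1, 0.4, 0.2, 0.2, 0.1))
        ids <- sprintf("g%04d", seq_along(sigs))
        sets <- lapply(sigs, function(sg) {
            mask <- as.integer(sub("S", "", sg))
            if (mask == 16L) return("E12")
            c("E1", "E4", "E6", "E9")[which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)]
        })
        names(sets) <- ids
        gst <- assignSignatures(sets, defaultStateGroupMap())
        target <- sample(ids, 40)
        list(gst = gst, target = target, pool = setdiff(ids, target))
    })
}

test_that("degenerate permutation inputs give statistic 0 and p = 1", {
    gst <- makePermGst(rep("S3", 13))
    ids <- signatureTable(gst)$gene_id
    pr <- matchedPermutationTest(ids[1:3], ids[4:13], gst, nPerm = 50,
                                 seed = 1)
    expect_equal(observedStat(pr), 0)
    expect_equal(pValue(pr), 1)
    expect_true(all(nullDraws(pr) == 0))
    expect_error(matchedPermutationTest(ids[1:3], ids[3:13], gst,
                                        nPerm = 10), "disjoint")
    expect_error(matchedPermutationTest(ids[1:3], ids[4:13], gst,
                                        nPerm = 0), "nPerm")
})

test_that("the empirical p-value is never zero and uses (b+1)/(n+1)", {
    fx <- permFixture()
    pr <- matchedPermutationTest(fx$target, fx$pool, fx$gst, nPerm = 999,
                                 seed = 5)
    b <- sum(nullDraws(pr) >= observedStat(pr))
    expect_equal(pValue(pr), (b + 1) / 1000)
    expect_gt(pValue(pr), 0)
})

test_that("TE-prevalence matching holds the TE count of every draw exactly", {
    fx <- permFixture(seed = 77)
    allIds <- c(fx$target, fx$pool)
    te <- withr::with_seed(11, stats::setNames(runif(length(allIds)) < 0.4,
                                               allIds))
    pr <- matchedPermutationTest(fx$target, fx$pool, fx$gst, nPerm = 200,
                                 matching = "TE_PREVALENCE", teFlags = te,
                                 seed = 2)
    draws <- pr@details$strata_draws
    sizes <- pr@details$strata_sizes
    expect_identical(sum(sizes), length(fx$target))
    expect_identical(sizes[1], sum(te[fx$target]))
    ## every permutation draw contains exactly the target's TE-stratum count
    for (s in seq_along(draws))
        expect_true(all(rowSums(draws[[s]]) == sizes[s]))
    ## infeasible matching is a clear error
    teAll <- stats::setNames(rep(TRUE, length(allIds)), allIds)
    teAll[fx$pool] <- FALSE
    expect_error(matchedPermutationTest(fx$target, fx$pool, fx$gst,
                                        nPerm = 10,
                                        matching = "TE_PREVALENCE",
                                        teFlags = teAll), "infeasible")
})

test_that("expression-window matching restricts the pool to 25% of the target median", {
    fx <- permFixture(seed = 31)
    allIds <- c(fx$target, fx$pool)
    expr <- withr::with_seed(13, stats::setNames(rlnorm(length(allIds), 2, 0.3),
                                                 allIds))
    pr <- matchedPermutationTest(fx$target, fx$pool, fx$gst, nPerm = 100,
                                 matching = "EXPRESSION_WINDOW",
                                 expression = expr, seed = 3)
    expect_s4_class(pr, "PermutationResult")
    med <- median(expr[fx$target])
    inWin <- sum(expr[fx$pool] >= 0.75 * med & expr[fx$pool] <= 1.25 * med)
    expect_gte(inWin, length(fx$target))
    ## narrow expression spread makes matching infeasible
    exprFar <- expr
    exprFar[fx$pool] <- exprFar[fx$pool] * 100
    expect_error(matchedPermutationTest(fx$target, fx$pool, fx$gst,
                                        nPerm = 10,
                                        matching = "EXPRESSION_WINDOW",
                                        expression = exprFar), "infeasible")
})

test_that("a planted silent-signature excess is detected at small p", {
    withr::with_seed(17, {
        poolSig <- sample(c("S3", "S1", "S7"), 300, replace = TRUE,
                          prob = c(0.6, 0.2, 0.2))
        targetSig <- sample(c("S8", "S12", "S3"), 40, replace = TRUE,
                            prob = c(0.5, 0.3, 0.2))
    })
    gst <- makePermGst(c(poolSig, targetSig))
    ids <- signatureTable(gst)$gene_id
    pr <- matchedPermutationTest(ids[301:340], ids[1:300], gst,
                                 nPerm = 10000, seed = 4)
    expect_lte(pValue(pr), 0.001)
})

test_that("the signature-location model reduces to group means and handles shifts", {
    ## two signatures, one location: coefficient = difference of group means
    expr <- stats::setNames(c(5, 6, 7, 1, 2, 3), sprintf("g%d", 1:6))
    sig <- stats::setNames(rep(c("S1", "S13"), each = 3), names(expr))
    loc <- stats::setNames(rep("AUTOSOME", 6), names(expr))
    fit <- signatureExpressionModel(expr, sig, loc)
    cf <- fit$coefficients
    expect_equal(cf$estimate[cf$term == "(Intercept)"], 6)
    expect_equal(cf$estimate[cf$term == "signatureS13"], 2 - 6)

    shifted <- signatureExpressionModel(expr + 10, sig, loc)
    expect_equal(shifted$coefficients$estimate[-1L], cf$estimate[-1L])
    expect_equal(shifted$coefficients$estimate[1L], cf$estimate[1L] + 10)

    ## balanced saturated two-way design: cell means recovered exactly
    expr2 <- stats::setNames(c(4, 4, 8, 8, 3, 3, 9, 9), sprintf("h%d", 1:8))
    sig2 <- stats::setNames(rep(c("S1", "S1", "S3", "S3"), 2), names(expr2))
    loc2 <- stats::setNames(rep(c("AUTOSOME", "PAR"), each = 4), names(expr2))
    fit2 <- suppressWarnings(signatureExpressionModel(expr2, sig2, loc2))
    cf2 <- stats::setNames(fit2$coefficients$estimate,
                           fit2$coefficients$term)
    expect_equal(unname(cf2["(Intercept)"]), 4)
    expect_equal(unname(cf2["signatureS3"]), 4)
    expect_equal(unname(cf2["locationPAR"]), -1)
    expect_equal(unname(cf2["signatureS3:locationPAR"]), 2)
})

test_that("signatures occurring on only one location are reported inestimable", {
    expr <- stats::setNames(c(1, 2, 5, 6, 7, 8), sprintf("g%d", 1:6))
    sig <- stats::setNames(c("S1", "S1", "S1", "S1", "S9", "S9"),
                           names(expr))
    loc <- stats::setNames(c("AUTOSOME", "AUTOSOME", "PAR", "PAR",
                             "PAR", "PAR"), names(expr))
    fit <- signatureExpressionModel(expr, sig, loc)
    cf <- fit$coefficients
    expect_true(any(!cf$estimable))
    expect_true(all(is.na(cf$p_value[!cf$estimable])))
})

test_that("interaction estimates are null when location has no effect", {
    withr::with_seed(29, {
        n <- 400
        sig <- sample(c("S1", "S3", "S13"), n, replace = TRUE)
        loc <- sample(c("AUTOSOME", "PAR"), n, replace = TRUE)
        mu <- c(S1 = 2, S3 = 5, S13 = 1)[sig]
        expr <- stats::setNames(rnorm(n, mu, 0.5), sprintf("g%03d", 1:n))
        fit <- signatureExpressionModel(expr,
                                        stats::setNames(sig, names(expr)),
                                        stats::setNames(loc, names(expr)))
        cf <- fit$coefficients
        inter <- cf[grepl(":", cf$term) & cf$estimable, ]
        expect_true(all(abs(inter$estimate) <= 3 * inter$std_error))
    })
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the printed-count arithmetic for segregating sites reproduces 0.004%", {
    expect_equal(percentSegregating(121, 2862827), 0.004)
    expect_error(percentSegregating(1, 0), "positive")
})
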