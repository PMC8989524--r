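test_that("reads are binned by their 5' start with a trailing partial bin", {
    lay <- tinyLayout(1100L)
    empty <- binSignal(GRanges(), lay, 200L)
    expect_identical(empty@values$chr1, numeric(6))  # ceil(1100/200)

    one <- binSignal(readsAt(250L), lay, 200L)
    expect_identical(one@values$chr1, c(0, 1, 0, 0, 0, 0))

    many <- binSignal(readsAt(c(0:9, 400:404)), lay, 200L)
    expect_identical(many@values$chr1, c(10, 0, 5, 0, 0, 0))
})

test_that("binning conserves the number of reads and rejects unknown chromosomes", {
    lay <- makeGenomeLayout(c(chr1 = 2000L, chr2 = 1000L))
    set.seed(4)
    starts <- sample(0:1900, 300, replace = TRUE)
    chroms <- sample(c("chr1", "chr2"), 300, replace = TRUE,
                     prob = c(0.7, 0.3))
    starts[chroms == "chr2"] <- starts[chroms == "chr2"] %% 900
    tr <- binSignal(GRanges(chroms, IRanges(starts + 1L, width = 30L)),
                    lay, 200L)
    expect_equal(sum(unlist(tr@values)), 300)
    expect_error(binSignal(readsAt(10L, chrom = "chrZ"), lay, 200L),
                 "chrZ")
})

test_that("SES scaling recovers trivial proportionality", {
    lay <- tinyLayout(2000L)
    set.seed(1)
    ctlv <- list(chr1 = rpois(10, 5) + 1)
    ctl <- makeBinnedTrack(ctlv, lay, 200L)
    ip_same <- makeBinnedTrack(ctlv, lay, 200L)
    r <- sesNormalize(ip_same, ctl)
    expect_equal(r$scale_factor, 1)
    expect_true(all(abs(unlist(r$ratio@values) - 1) < 1e-12))

    ip2 <- makeBinnedTrack(list(chr1 = 2 * ctlv$chr1), lay, 200L)
    r2 <- sesNormalize(ip2, ctl)
    expect_equal(r2$scale_factor, 2)
    expect_true(all(abs(unlist(r2$ratio@values) - 1) < 1e-12))
    expect_error(sesNormalize(ip2, makeBinnedTrack(list(chr1 = numeric(10)),
                                                   lay, 200L)),
                 "all-zero control")
})

test_that("SES scale factor matches a direct cumulative-difference scan and is rescale-invariant", {
    lay <- tinyLayout(40000L)  # 200 bins
    set.seed(11)
    ctlv <- rpois(200, 10) + 1
    ipv <- rpois(200, 10)
    enriched <- sample(200, 20)
    ipv[enriched] <- ipv[enriched] + rpois(20, 60)
    ip <- makeBinnedTrack(list(chr1 = as.numeric(ipv)), lay, 200L)
    ctl <- makeBinnedTrack(list(chr1 = as.numeric(ctlv)), lay, 200L)
    got <- sesNormalize(ip, ctl)$scale_factor

    ## brute-force scan over every candidate background size k
    ord <- order(ipv)
    diffs <- vapply(seq_len(200), function(k) {
        sum(ctlv[ord][1:k]) / sum(ctlv) - sum(ipv[ord][1:k]) / sum(ipv)
    }, 0)
    k <- which.max(diffs)
    expect_equal(got, sum(ipv[ord][1:k]) / sum(ctlv[ord][1:k]))

    ## globally rescaling both tracks leaves the factor unchanged, while
    ## rescaling only the IP scales it proportionally
    ip3 <- makeBinnedTrack(list(chr1 = 3 * as.numeric(ipv)), lay, 200L)
    ctl3 <- makeBinnedTrack(list(chr1 = 3 * as.numeric(ctlv)), lay, 200L)
    expect_equal(sesNormalize(ip3, ctl3)$scale_factor, got)
    expect_equal(sesNormalize(ip3, ctl)$scale_factor, 3 * got)
})

test_that("Poisson binarization calls match a hand-computed tail at lambda 2", {
    ## 13 bins, IP total 26, uniform control total 13 -> lambda = 2 per bin.
    ## Direct tail summation: P(X>=20|2) < 1e-4 < P(X>=5|2), so only the
    ## 20-read bin is called.
    tail2 <- function(x) 1 - sum(exp(-2) * 2^(0:(x - 1)) / factorial(0:(x - 1)))
    expect_lt(tail2(20), 1e-4)
    expect_gt(tail2(5), 1e-4)
    lay <- tinyLayout(2600L)
    ip <- makeBinnedTrack(list(chr1 = c(0, 1, 5, 20, rep(0, 9))), lay, 200L)
    ctl <- makeBinnedTrack(list(chr1 = rep(1, 13)), lay, 200L)
    expect_identical(unname(unlist(binarizeTrack(ip, ctl))),
                     c(0L, 0L, 0L, 1L, rep(0L, 9)))
})

test_that("binarization degenerate cases: zero IP, IP equal to control", {
    lay <- tinyLayout(800L)
    zero <- makeBinnedTrack(list(chr1 = numeric(4)), lay, 200L)
    expect_identical(unname(unlist(binarizeTrack(zero, NULL))),
                     rep(0L, 4))
    same <- makeBinnedTrack(list(chr1 = c(3, 4, 5, 6)), lay, 200L)
    expect_identical(unname(unlist(binarizeTrack(same, same))),
                     rep(0L, 4))
})

test_that("binarization is monotone in the IP count", {
    lay <- tinyLayout(4000L)
    set.seed(21)
    for (rep_ in 1:20) {
        ipv <- rpois(20, 4)
        ctlv <- rpois(20, 2) + 1
        ip <- makeBinnedTrack(list(chr1 = as.numeric(ipv)), lay, 200L)
        ctl <- makeBinnedTrack(list(chr1 = as.numeric(ctlv)), lay, 200L)
        base <- unlist(binarizeTrack(ip, ctl))
        i <- sample(20, 1)
        ipv2 <- ipv
        ipv2[i] <- ipv2[i] + sample(1:30, 1)
        ## hold lambda fixed at the original background while raising one bin
        lam <- pmax(ctlv * sum(ipv) / sum(ctlv), 1)
        call1 <- as.integer(ppois(ipv - 1, lam, lower.tail = FALSE) <= 1e-4)
        call2 <- as.integer(ppois(ipv2 - 1, lam, lower.tail = FALSE) <= 1e-4)
        expect_true(all(call2 >= call1))
        expect_identical(call1, unname(unlist(binarizeTrack(ip, ctl))))
    }
})

test_that("segmentations round-trip losslessly and merge adjacent same-state tiles", {
    seg <- segFromTiles(c(0, 200, 400), c(200, 400, 600),
                        c("E1", "E1", "E9"), K = 12L)
    path <- withr::local_tempfile(fileext = ".bed")
    writeSegmentation(seg, path)
    lines <- readLines(path)
    expect_identical(lines[-1L],
                     c("chr1\t0\t400\tE1", "chr1\t400\t600\tE9"))
    back <- readSegmentation(path)
    expect_identical(binSize(back), 200L)
    again <- withr::local_tempfile(fileext = ".bed")
    writeSegmentation(back, again)
    expect_identical(readLines(path), readLines(again))
})

test_that("malformed segmentation files are rejected", {
    path <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("#binSize=200 sample= K=12", "chr1\t0\t200\tX9"), path)
    expect_error(readSegmentation(path), "unknown state label")
    writeLines(c("#binSize=200 sample= K=12", "chr1\t50\t200\tE1"), path)
    expect_error(readSegmentation(path), "non-bin-aligned")
})

test_that("replicate binary matrices combine by OR or AND per bin", {
    lay <- tinyLayout(1000L)
    a <- makeBinaryMatrix(list(m1 = list(chr1 = c(1L, 0L, 0L, 1L, 0L))),
                          lay, 200L)
    b <- makeBinaryMatrix(list(m1 = list(chr1 = c(0L, 0L, 1L, 1L, 0L))),
                          lay, 200L)
    expect_identical(unname(combineReplicates(a, b, "or")@data[, 1L]),
                     c(1L, 0L, 1L, 1L, 0L))
    expect_identical(unname(combineReplicates(a, b, "and")@data[, 1L]),
                     c(0L, 0L, 0L, 1L, 0L))
})
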