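test_that("a one-state model reduces to observed mark frequencies", {
    lay <- tinyLayout(2000L)
    set.seed(8)
    cols <- list(a = list(chr1 = rbinom(10, 1, 0.3)),
                 b = list(chr1 = rbinom(10, 1, 0.7)))
    bm <- makeBinaryMatrix(cols, lay, 200L)
    m <- fitHMM(bm, K = 1, seed = 1)
    expect_equal(unname(emissionProbs(m)[1, ]),
                 unname(colMeans(bm@data)), tolerance = 1e-9)
    expect_identical(transitionProbs(m), matrix(1, 1, 1))
    seg <- decodeStates(m, bm)
    expect_length(tiles(seg), 1L)
    expect_identical(mcols(tiles(seg))$state, "E1")
})

test_that("fitting is bit-reproducible given data, K and seed", {
    lay <- tinyLayout(20000L)
    truth <- randomHMM(2, 3, seed = 2)
    sim <- simulateBinaryMatrix(truth, lay, 200L, seed = 5)
    m1 <- fitHMM(sim$bm, K = 2, seed = 9, maxIter = 30)
    m2 <- fitHMM(sim$bm, K = 2, seed = 9, maxIter = 30)
    expect_identical(emissionProbs(m1), emissionProbs(m2))
    expect_identical(transitionProbs(m1), transitionProbs(m2))
    expect_identical(m1@metadata$logLik, m2@metadata$logLik)
    m3 <- fitHMM(sim$bm, K = 2, seed = 10, maxIter = 30)
    expect_false(identical(emissionProbs(m1), emissionProbs(m3)))
})

test_that("forward-backward posteriors equal exhaustive path enumeration", {
    set.seed(13)
    for (case in 1:12) {
        K <- sample(1:3, 1)
        M <- sample(2:4, 1)
        T_ <- sample(2:8, 1)
        model <- randomHMM(K, M, seed = 100 + case)
        X <- matrix(rbinom(T_ * M, 1, 0.5), T_, M)
        colnames(X) <- marks(model)
        lay <- tinyLayout(T_ * 200L)
        cols <- lapply(seq_len(M), function(j) list(chr1 = X[, j]))
        names(cols) <- marks(model)
        bm <- makeBinaryMatrix(cols, lay, 200L)
        got <- statePosteriors(model, bm)
        oracle <- enumPosterior(model, X)
        expect_lt(max(abs(got - oracle$gamma)), 1e-9)
        expect_true(all(abs(rowSums(got) - 1) < 1e-9))
    }
})

test_that("EM log-likelihood is non-decreasing on arbitrary inputs", {
    lay <- tinyLayout(6000L)
    for (seed in 1:5) {
        set.seed(seed)
        cols <- list(a = list(chr1 = rbinom(30, 1, runif(1, 0.2, 0.8))),
                     b = list(chr1 = rbinom(30, 1, runif(1, 0.2, 0.8))))
        bm <- makeBinaryMatrix(cols, lay, 200L)
        m <- fitHMM(bm, K = 3, seed = seed, maxIter = 60)
        expect_true(all(diff(m@metadata$logLik) > -1e-8))
    }
})

test_that("well-separated two-state truth is recovered and decoded at >= 99%", {
    E <- matrix(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1), 2, 3, byrow = TRUE)
    truth <- new("BernoulliHMM", K = 2L, emission = E,
                 transition = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2),
                 initial = c(0.5, 0.5), marks = c("a", "b", "c"),
                 metadata = list())
    lay <- tinyLayout(4e6)  # 20k bins
    sim <- simulateBinaryMatrix(truth, lay, 200L, seed = 7)
    fit <- fitHMM(sim$bm, K = 2, seed = 3)
    ## match fitted states to truth by emission distance
    d11 <- mean(abs(emissionProbs(fit)[1, ] - E[1, ]))
    d12 <- mean(abs(emissionProbs(fit)[1, ] - E[2, ]))
    map <- if (d11 < d12) c(1L, 2L) else c(2L, 1L)
    expect_lt(mean(abs(emissionProbs(fit)[order(map), ] - E)), 0.05)
    dec <- max.col(statePosteriors(fit, sim$bm), ties.method = "first")
    expect_gte(mean(map[dec] == sim$states), 0.99)
})

test_that("decoding commutes with state relabelling", {
    model <- randomHMM(3, 4, seed = 33)
    lay <- tinyLayout(20000L)
    sim <- simulateBinaryMatrix(model, lay, 200L, seed = 6)
    perm <- c(3L, 1L, 2L)  # state k of the permuted model = state perm[k]
    permuted <- new("BernoulliHMM", K = 3L,
                    emission = emissionProbs(model)[perm, ],
                    transition = transitionProbs(model)[perm, perm],
                    initial = initialProbs(model)[perm],
                    marks = marks(model), metadata = list())
    d1 <- max.col(statePosteriors(model, sim$bm), ties.method = "first")
    d2 <- max.col(statePosteriors(permuted, sim$bm), ties.method = "first")
    expect_identical(perm[d2], d1)
})

test_that("posterior and Viterbi decodings agree on well-separated data", {
    E <- matrix(c(0.9, 0.9, 0.1, 0.1, 0.1, 0.9), 2, 3, byrow = TRUE)
    truth <- new("BernoulliHMM", K = 2L, emission = E,
                 transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2),
                 initial = c(0.5, 0.5), marks = c("a", "b", "c"),
                 metadata = list())
    lay <- tinyLayout(2e5)
    sim <- simulateBinaryMatrix(truth, lay, 200L, seed = 2)
    sp <- decodeStates(truth, sim$bm, method = "posterior")
    sv <- decodeStates(truth, sim$bm, method = "viterbi")
    toBins <- function(seg) {
        gr <- tiles(seg)
        rep(mcols(gr)$state, (end(gr) - start(gr) + 1L) %/% 200L +
                ((end(gr) - start(gr) + 1L) %% 200L > 0L))
    }
    expect_gt(mean(toBins(sp) == toBins(sv)), 0.98)
})

test_that("state similarity recovers permutations and penalises complements", {
    m <- randomHMM(4, 5, seed = 55)
    self <- stateSimilarity(m, m)
    expect_true(all(abs(self$correlation - 1) < 1e-12))

    perm <- c(2L, 4L, 1L, 3L)
    mp <- new("BernoulliHMM", K = 4L, emission = emissionProbs(m)[perm, ],
              transition = transitionProbs(m)[perm, perm],
              initial = initialProbs(m)[perm], marks = marks(m),
              metadata = list())
    sim <- stateSimilarity(m, mp)
    expect_identical(sim$best_state_b, paste0("E", order(perm)))
    expect_true(all(abs(sim$correlation - 1) < 1e-12))

    ## a complemented state anticorrelates perfectly and is never preferred
    E2 <- emissionProbs(m)
    E2[2, ] <- 1 - emissionProbs(m)[1, ]
    mc <- new("BernoulliHMM", K = 4L, emission = pmin(pmax(E2, 1e-6), 1 - 1e-6),
              transition = transitionProbs(m), initial = initialProbs(m),
              marks = marks(m), metadata = list())
    compCor <- cor(emissionProbs(m)[1, ], emissionProbs(mc)[2, ])
    expect_equal(compCor, -1, tolerance = 1e-9)
    simc <- stateSimilarity(m, mc)
    expect_gt(simc$correlation[1], 0)
    expect_false(simc$best_state_b[1] == "E2")

    ## constant rows get correlation 0 by definition
    mFlat <- new("BernoulliHMM", K = 1L,
                 emission = matrix(0.5, 1, 5), transition = matrix(1, 1, 1),
                 initial = 1, marks = marks(m), metadata = list())
    expect_identical(stateSimilarity(mFlat, m)$correlation, 0)
})

test_that("state-count selection spans the requested range and flags the truth", {
    ## 4 well-separated true states; a larger reference collapses cleanly
    E <- rbind(c(0.9, 0.1, 0.1, 0.1), c(0.1, 0.9, 0.1, 0.1),
               c(0.1, 0.1, 0.9, 0.1), c(0.1, 0.1, 0.1, 0.9))
    A <- matrix(0.1 / 3, 4, 4); diag(A) <- 0.9
    truth <- new("BernoulliHMM", K = 4L, emission = E, transition = A,
                 initial = rep(0.25, 4), marks = paste0("m", 1:4),
                 metadata = list())
    lay <- tinyLayout(1.6e6)  # 8k bins
    sim <- simulateBinaryMatrix(truth, lay, 200L, seed = 19)
    sel <- selectStateCount(sim$bm, kMax = 6L, kMin = 2L, seed = 1L,
                            maxIter = 60L, init = "patterns")
    expect_identical(sel$curve$k, 2:5)
    expect_true(sel$K >= 3L && sel$K <= 5L)
    one <- selectStateCount(sim$bm, kMax = 3L, kMin = 3L, seed = 1L,
                            maxIter = 10L)
    expect_identical(one$K, 3L)
    expect_identical(nrow(one$curve), 0L)
    expect_error(selectStateCount(sim$bm, kMax = 2L, kMin = 3L), "kMin")
})

test_that("models serialize to a TSV bundle and back", {
    m <- randomHMM(3, 4, seed = 77)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeHMM(m, path)
    back <- readHMM(path)
    expect_equal(emissionProbs(back), emissionProbs(m), tolerance = 1e-8)
    expect_equal(transitionProbs(back), transitionProbs(m), tolerance = 1e-8)
    expect_equal(initialProbs(back), initialProbs(m), tolerance = 1e-8)
    expect_identical(marks(back), marks(m))
})

test_that("mark-order mismatches are rejected", {
    lay <- tinyLayout(1000L)
    a <- makeBinaryMatrix(list(m1 = list(chr1 = rep(0L, 5)),
                               m2 = list(chr1 = rep(1L, 5))), lay, 200L)
    b <- makeBinaryMatrix(list(m2 = list(chr1 = rep(0L, 5)),
                               m1 = list(chr1 = rep(1L, 5))), lay, 200L)
    expect_error(fitHMM(list(a, b), K = 2), "mark order")
    m <- fitHMM(a, K = 1, seed = 1)
    expect_error(decodeStates(m, b), "mark order")
})
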