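## Baum-Welch fitting, decoding and model selection for the joint
## multivariate Bernoulli HMM over binarized chromatin marks.

## Split a BinaryMatrix into per-chromosome observation sequences.
obsSequences <- function(bm) {
    idx <- split(seq_len(nrow(bm@data)), factor(bm@rowChrom,
                                                levels = unique(bm@rowChrom)))
    lapply(idx, function(i) bm@data[i, , drop = FALSE])
}

## Per-bin per-state emission likelihoods for a 0/1 observation matrix.
emissionLik <- function(X, E) {
    logE <- log(E); log1E <- log1p(-E)
    exp(X %*% t(logE) + (1 - X) %*% t(log1E))
}

clipEmission <- function(E) pmin(pmax(E, EMISSION_EPS), 1 - EMISSION_EPS)

## Evaluate RNG-dependent code under a seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Fit a joint multivariate Bernoulli HMM by Baum-Welch
#'
#' Learns one K-state model from all supplied observation sets together: each
#' chromosome of each [BinaryMatrix-class] (typically one matrix per sex) is
#' an independent observation sequence sharing a single parameter set, so
#' male and female genomes are segmented with a common state vocabulary.
#'
#' Emission probabilities are initialised uniformly in `[0.1, 0.9]` from the
#' seeded generator; transition rows and the initial distribution start
#' uniform.  EM runs until the log-likelihood improvement drops below `tol`
#' or `maxIter` is reached.  Emissions are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param observations a [BinaryMatrix-class] or list of them (same mark
#'   order).
#' @param K number of hidden states.
#' @param seed RNG seed for the initialisation; fits are reproducible given
#'   `(data, K, seed, init)`.
#' @param maxIter maximum EM iterations (default 200).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param init `"uniform"` (emissions drawn uniformly in `[0.1, 0.9]`) or
#'   `"patterns"`: emission rows seeded from the K most frequent distinct
#'   observed mark patterns (an information-based initialisation in the
#'   spirit of the segmentation tools used in the field), which anchors rare
#'   combinatorial states that a flat random start tends to merge away.
#' @return a [BernoulliHMM-class].
#' @export
fitHMM <- function(observations, K, seed = 1L, maxIter = 200L, tol = 1e-4,
                   init = c("uniform", "patterns")) {
    init <- match.arg(init)
    if (K < 1L) stop("K must be >= 1")
    if (methods::is(observations, "BinaryMatrix"))
        observations <- list(observations)
    if (length(observations) == 0L) stop("no observations supplied")
    markSets <- lapply(observations, function(o) o@marks)
    if (length(unique(markSets)) != 1L)
        stop("mark order differs between observation sets")
    mk <- markSets[[1L]]
    seqs <- unlist(lapply(observations, obsSequences), recursive = FALSE)
    seqs <- seqs[vapply(seqs, nrow, 0L) > 0L]
    if (length(seqs) == 0L) stop("empty observations")
    M <- length(mk)
    K <- as.integer(K)

    E <- withSeed(seed, {
        if (init == "patterns") {
            X <- do.call(rbind, seqs)
            id <- as.integer(X %*% 2^(seq_len(M) - 1L))
            top <- as.integer(names(sort(table(id), decreasing = TRUE)))
            top <- utils::head(top, K)
            pat <- t(vapply(top, function(v)
                as.integer(bitwAnd(v, 2^(seq_len(M) - 1L)) > 0L),
                integer(M)))
            extra <- K - nrow(pat)
            if (extra > 0L)
                pat <- rbind(pat, matrix(stats::runif(extra * M), extra, M))
            pat * 0.8 + 0.1
        } else {
            matrix(stats::runif(K * M, 0.1, 0.9), K, M)
        }
    })
    colnames(E) <- mk
    A <- matrix(1 / K, K, K)
    pi0 <- rep(1 / K, K)

    llTrace <- numeric(0)
    iter <- 0L
    converged <- FALSE
    repeat {
        iter <- iter + 1L
        gammaSum <- numeric(K)
        gammaX <- matrix(0, K, M)
        xiSum <- matrix(0, K, K)
        pi1 <- numeric(K)
        ll <- 0
        for (X in seqs) {
            B <- emissionLik(X, E)
            fb <- .fb_pass(B, pi0, A)
            g <- fb$gamma
            gammaSum <- gammaSum + colSums(g)
            gammaX <- gammaX + t(g) %*% X
            xiSum <- xiSum + fb$xi
            pi1 <- pi1 + g[1L, ]
            ll <- ll + fb$loglik
        }
        llTrace <- c(llTrace, ll)
        Enew <- clipEmission(gammaX / pmax(gammaSum, .Machine$double.xmin))
        rs <- rowSums(xiSum)
        Anew <- A
        if (K > 1L) {
            occ <- rs > 0
            Anew[occ, ] <- xiSum[occ, , drop = FALSE] / rs[occ]
        } else Anew <- matrix(1, 1L, 1L)
        piNew <- pi1 / length(seqs)
        piNew <- piNew / sum(piNew)
        done <- iter >= maxIter ||
            (iter > 1L && (ll - llTrace[iter - 1L]) < tol)
        if (iter > 1L && (ll - llTrace[iter - 1L]) < tol) converged <- TRUE
        if (done) break
        E <- Enew; A <- Anew; pi0 <- piNew
    }
    colnames(E) <- mk
    dimnames(A) <- NULL
    new("BernoulliHMM", K = K, emission = E, transition = A,
        initial = pi0, marks = mk,
        metadata = list(seed = as.integer(seed), iterations = iter,
                        logLik = llTrace, converged = converged))
}

#' Per-bin posterior state probabilities
#'
#' Forward-backward posteriors for every bin of a [BinaryMatrix-class]; each
#' row sums to one.
#'
#' @param model a [BernoulliHMM-class].
#' @param bm a [BinaryMatrix-class] with the model's mark order.
#' @return numeric matrix, bins x states.
#' @export
statePosteriors <- function(model, bm) {
    if (!identical(marks(model), marks(bm)))
        stop("mark order of observations does not match the model")
    out <- lapply(obsSequences(bm), function(X) {
        B <- emissionLik(X, model@emission)
        .fb_pass(B, model@initial, model@transition)$gamma
    })
    do.call(rbind, out)
}

#' Decode a genome segmentation from a fitted model
#'
#' Assigns each bin the state maximising the forward-backward posterior
#' (ties broken toward the lowest state index), or the Viterbi path, then
#' merges consecutive equal-state bins into tiles.
#'
#' @param model a [BernoulliHMM-class].
#' @param bm a [BinaryMatrix-class].
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @return a [Segmentation-class].
#' @export
decodeStates <- function(model, bm, method = c("posterior", "viterbi")) {
    method <- match.arg(method)
    if (!identical(marks(model), marks(bm)))
        stop("mark order of observations does not match the model")
    seqs <- obsSequences(bm)
    states <- lapply(seqs, function(X) {
        if (method == "posterior") {
            B <- emissionLik(X, model@emission)
            g <- .fb_pass(B, model@initial, model@transition)$gamma
            max.col(g, ties.method = "first")
        } else {
            logB <- X %*% t(log(model@emission)) +
                (1 - X) %*% t(log1p(-model@emission))
            .viterbi_pass(logB, log(model@initial), log(model@transition))
        }
    })
    binStatesToSegmentation(states, bm@seqlengths, bm@binSize, model@K,
                            bm@sample)
}

#' Emission-parameter similarity between two models
#'
#' For each state of `model_a`, the best-matching state of `model_b` by
#' Pearson correlation of emission vectors.  Constant emission rows have
#' correlation defined as 0.
#'
#' @param model_a,model_b [BernoulliHMM-class] objects over the same marks.
#' @return data.frame with columns `state_a`, `best_state_b`, `correlation`.
#' @export
stateSimilarity <- function(model_a, model_b) {
    if (!identical(marks(model_a), marks(model_b)))
        stop("models are over different mark sets")
    Ea <- model_a@emission; Eb <- model_b@emission
    corRow <- function(x, y) {
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
        stats::cor(x, y)
    }
    best <- t(vapply(seq_len(nrow(Ea)), function(i) {
        cors <- vapply(seq_len(nrow(Eb)), function(j) corRow(Ea[i, ], Eb[j, ]),
                       0)
        j <- which.max(cors)
        c(j, cors[j])
    }, numeric(2)))
    data.frame(state_a = paste0("E", seq_len(nrow(Ea))),
               best_state_b = paste0("E", as.integer(best[, 1L])),
               correlation = best[, 2L])
}

#' Choose the number of HMM states by cross-model emission correlation
#'
#' Fits a reference model with `kMax` states, then for each smaller k records
#' how well every reference state is recovered (its best emission-vector
#' correlation in the k-state model).  The chosen K is the smallest k whose
#' worst-recovered reference state still correlates at or above
#' `similarityFloor`; if no k qualifies, `kMax` is returned.
#'
#' @param observations as for [fitHMM()].
#' @param kMax,kMin state-count range (defaults 17 and 8).
#' @param seed RNG seed; the k-state fit uses `seed + k`.
#' @param similarityFloor minimum acceptable worst-state correlation
#'   (default 0.9).
#' @param ... passed to [fitHMM()] (e.g. `maxIter`, `tol`).
#' @return list with `K` (chosen state count), `curve` (data.frame `k`,
#'   `min_correlation`) and `reference` (the kMax-state model).
#' @export
selectStateCount <- function(observations, kMax = 17L, kMin = 8L, seed = 1L,
                             similarityFloor = 0.9, ...) {
    if (kMin > kMax) stop("kMin must be <= kMax")
    reference <- fitHMM(observations, K = kMax, seed = seed + kMax, ...)
    if (kMin == kMax)
        return(list(K = as.integer(kMax),
                    curve = data.frame(k = integer(0),
                                       min_correlation = numeric(0)),
                    reference = reference))
    ks <- seq(kMax - 1L, kMin)
    minCor <- vapply(ks, function(k) {
        m <- fitHMM(observations, K = k, seed = seed + k, ...)
        min(stateSimilarity(reference, m)$correlation)
    }, 0)
    curve <- data.frame(k = as.integer(ks), min_correlation = minCor)
    ok <- curve$k[curve$min_correlation >= similarityFloor]
    K <- if (length(ok) > 0L) min(ok) else as.integer(kMax)
    list(K = as.integer(K), curve = curve[order(curve$k), ],
         reference = reference)
}

#' Serialize / deserialize a BernoulliHMM as a TSV bundle
#'
#' One plain-text file with commented section markers holding the emission
#' matrix, transition matrix, initial distribution and fit metadata.
#'
#' @param model a [BernoulliHMM-class].
#' @param path file path.
#' @return `path` (write) or a [BernoulliHMM-class] (read).
#' @export
writeHMM <- function(model, path) {
    con <- file(path, "w")
    on.exit(close(con))
    ll <- model@metadata$logLik
    ll <- if (length(ll) > 0L) utils::tail(ll, 1L) else NA_real_
    writeLines(sprintf("#chromsig BernoulliHMM K=%d seed=%d iterations=%d logLik=%.10g",
                       model@K, model@metadata$seed %||% NA_integer_,
                       model@metadata$iterations %||% NA_integer_, ll),
               con)
    writeLines(paste0("#section emission\nstate\t",
                      paste(model@marks, collapse = "\t")), con)
    for (k in seq_len(model@K))
        writeLines(paste(c(paste0("E", k),
                           sprintf("%.10g", model@emission[k, ])),
                         collapse = "\t"), con)
    writeLines("#section transition", con)
    for (k in seq_len(model@K))
        writeLines(paste(sprintf("%.10g", model@transition[k, ]),
                         collapse = "\t"), con)
    writeLines("#section initial", con)
    writeLines(paste(sprintf("%.10g", model@initial), collapse = "\t"), con)
    invisible(path)
}

#' @rdname writeHMM
#' @export
readHMM <- function(path) {
    lines <- readLines(path)
    hd <- lines[1L]
    K <- as.integer(sub(".*K=([0-9]+).*", "\\1", hd))
    emStart <- grep("^#section emission", lines) + 1L
    mk <- strsplit(lines[emStart], "\t")[[1L]][-1L]
    em <- do.call(rbind, lapply(lines[emStart + seq_len(K)], function(l) {
        as.numeric(strsplit(l, "\t")[[1L]][-1L])
    }))
    colnames(em) <- mk
    trStart <- grep("^#section transition", lines)
    tr <- do.call(rbind, lapply(lines[trStart + seq_len(K)], function(l)
        as.numeric(strsplit(l, "\t")[[1L]])))
    inStart <- grep("^#section initial", lines)
    init <- as.numeric(strsplit(lines[inStart + 1L], "\t")[[1L]])
    new("BernoulliHMM", K = K, emission = clipEmission(em),
        transition = tr / rowSums(tr), initial = init / sum(init),
        marks = mk, metadata = list(source = path))
}
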