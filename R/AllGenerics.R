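#' Accessors for chromsig classes
#'
#' Small accessor generics in the Bioconductor style; user code should use
#' these rather than reaching into slots.
#'
#' @param x a chromsig object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("marks", function(x) standardGeneric("marks"))
#' @rdname accessors
#' @export
setGeneric("emissionProbs", function(x) standardGeneric("emissionProbs"))
#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))
#' @rdname accessors
#' @export
setGeneric("initialProbs", function(x) standardGeneric("initialProbs"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("tiles", function(x) standardGeneric("tiles"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))
#' @rdname accessors
#' @export
setGeneric("signatureTable", function(x) standardGeneric("signatureTable"))
#' @rdname accessors
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))
#' @rdname accessors
#' @export
setGeneric("nullDraws", function(x) standardGeneric("nullDraws"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setMethod("binSize", "BinnedTrack", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "BinaryMatrix", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "Segmentation", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("marks", "BinnedTrack", function(x) x@mark)
#' @rdname accessors
#' @export
setMethod("marks", "BinaryMatrix", function(x) x@marks)
#' @rdname accessors
#' @export
setMethod("marks", "BernoulliHMM", function(x) x@marks)
#' @rdname accessors
#' @export
setMethod("emissionProbs", "BernoulliHMM", function(x) x@emission)
#' @rdname accessors
#' @export
setMethod("transitionProbs", "BernoulliHMM", function(x) x@transition)
#' @rdname accessors
#' @export
setMethod("initialProbs", "BernoulliHMM", function(x) x@initial)
#' @rdname accessors
#' @export
setMethod("nStates", "BernoulliHMM", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("tiles", "Segmentation", function(x) x@tiles)
#' @rdname accessors
#' @export
setMethod("regions", "GenomeLayout", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) x@seqlengths)
#' @rdname accessors
#' @export
setMethod("sampleLabel", "BinnedTrack", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("sampleLabel", "BinaryMatrix", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("sampleLabel", "Segmentation", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("sampleLabel", "GeneSignatureTable", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("signatureTable", "GeneSignatureTable", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("observedStat", "PermutationResult", function(x) x@observed)
#' @rdname accessors
#' @export
setMethod("nullDraws", "PermutationResult", function(x) x@nullDraws)
#' @rdname accessors
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

setMethod("show", "GenomeLayout", function(object) {
    cat(sprintf("GenomeLayout: %d chromosomes, %s bp total\n",
                length(object@seqlengths),
                format(sum(as.numeric(object@seqlengths)), big.mark = ",")))
    tab <- table(factor(mcols(object@regions)$region_class,
                        levels = REGION_CLASSES))
    cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
})

setMethod("show", "BinnedTrack", function(object) {
    cat(sprintf("BinnedTrack '%s' [%s]: %d-bp bins, %d chromosomes, total signal %.0f\n",
                object@mark, object@sample, object@binSize,
                length(object@values), sum(vapply(object@values, sum, 0))))
})

setMethod("show", "BinaryMatrix", function(object) {
    cat(sprintf("BinaryMatrix [%s]: %d bins x %d marks (%d-bp bins), density %.3f\n",
                object@sample, nrow(object@data), ncol(object@data),
                object@binSize, mean(object@data)))
})

setMethod("show", "BernoulliHMM", function(object) {
    ll <- object@metadata$logLik
    ll <- if (length(ll) > 0L) utils::tail(ll, 1L) else NA_real_
    cat(sprintf("BernoulliHMM: K=%d states, %d marks, logLik=%.2f (%d iterations)\n",
                object@K, length(object@marks), ll,
                object@metadata$iterations %||% NA_integer_))
})

setMethod("show", "Segmentation", function(object) {
    cat(sprintf("Segmentation [%s]: %d tiles, K=%d, %d-bp bins\n",
                object@sample, length(object@tiles), object@K, object@binSize))
})

setMethod("show", "GeneSignatureTable", function(object) {
    cat(sprintf("GeneSignatureTable [%s]: %d genes, %d distinct signatures\n",
                object@sample, nrow(object@table),
                length(unique(object@table$signature))))
})

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf("PermutationResult: observed chi-square %.3f, p = %.4g (matching %s, n_perm %d, seed %d)\n",
                object@observed, object@pValue, object@matching,
                object@nPerm, object@seed))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
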