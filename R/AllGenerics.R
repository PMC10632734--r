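#' Accessors for onionnet classes
#'
#' `geneIds()`/`sampleIds()` return axis labels irrespective of orientation;
#' `scoreMatrix()` returns the values in a requested orientation (default:
#' genes as rows, the canonical in-memory layout); `orientation()` reports
#' the stored layout. `nodeIds()`/`weightMatrix()` apply to the network
#' classes, `normMethod()`/`hyperparameter()` to [NormalizedLayer-class].
#'
#' @param x an onionnet object.
#' @param ... further arguments passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x, ...) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
#' @rdname accessors
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))
#' @rdname accessors
#' @export
setGeneric("hyperparameter", function(x) standardGeneric("hyperparameter"))

#' @rdname accessors
#' @export
setMethod("orientation", "GeneEffectMatrix", function(x) x@orientation)

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneEffectMatrix", function(x) {
    if (x@orientation == "genes_as_rows") rownames(x@values) else colnames(x@values)
})

#' @rdname accessors
#' @export
setMethod("sampleIds", "GeneEffectMatrix", function(x) {
    if (x@orientation == "genes_as_rows") colnames(x@values) else rownames(x@values)
})

#' @rdname accessors
#' @param orientation requested layout of the returned matrix.
#' @export
setMethod("scoreMatrix", "GeneEffectMatrix",
    function(x, orientation = c("genes_as_rows", "samples_as_rows")) {
        orientation <- match.arg(orientation)
        if (orientation == x@orientation) x@values else t(x@values)
    })

#' @rdname accessors
#' @export
setMethod("normMethod", "NormalizedLayer", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("hyperparameter", "NormalizedLayer", function(x) x@hyperparameter)

#' @rdname accessors
#' @export
setMethod("nodeIds", "SimilarityNetwork", function(x) rownames(x@weights))
#' @rdname accessors
#' @export
setMethod("nodeIds", "AffinityNetwork", function(x) rownames(x@weights))
#' @rdname accessors
#' @export
setMethod("nodeIds", "FusedNetwork", function(x) rownames(x@weights))

#' @rdname accessors
#' @export
setMethod("weightMatrix", "SimilarityNetwork", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("weightMatrix", "AffinityNetwork", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("weightMatrix", "FusedNetwork", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("dim", "GeneEffectMatrix", function(x) dim(x@values))

#' Complexes of a co-annotation standard
#' @param x a [CoAnnotationStandard-class].
#' @return named list of gene-id vectors (`complexes`), or the union of all
#'   member genes (`geneUniverse`).
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))
#' @rdname complexes
#' @export
setMethod("complexes", "CoAnnotationStandard", function(x) x@complexes)

#' @rdname complexes
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname complexes
#' @export
setMethod("geneUniverse", "CoAnnotationStandard",
    function(x) sort(unique(unlist(x@complexes, use.names = FALSE))))

setMethod("show", "GeneEffectMatrix", function(object) {
    cat(sprintf("%s: %d genes x %d samples (%s)\n", class(object),
        length(geneIds(object)), length(sampleIds(object)),
        object@orientation))
    nNA <- sum(is.na(object@values))
    if (nNA) cat(sprintf("  missing entries: %d\n", nNA))
    if (is(object, "NormalizedLayer"))
        cat(sprintf("  method: %s, hyperparameter: %s\n", object@method,
            format(object@hyperparameter)))
})

setMethod("show", "SimilarityNetwork", function(object) {
    cat(sprintf("SimilarityNetwork (%s): %d nodes\n", object@kind,
        nrow(object@weights)))
})

setMethod("show", "AffinityNetwork", function(object) {
    cat(sprintf("AffinityNetwork: %d nodes (sigma = %g, k = %d)\n",
        nrow(object@weights), object@sigma, object@kNeighbors))
})

setMethod("show", "FusedNetwork", function(object) {
    cat(sprintf("FusedNetwork: %d nodes, %d fused layers\n",
        nrow(object@weights), length(object@provenance)))
})

setMethod("show", "CoAnnotationStandard", function(object) {
    sizes <- lengths(object@complexes)
    cat(sprintf("CoAnnotationStandard: %d complexes, %d genes (sizes %s)\n",
        length(object@complexes), length(geneUniverse(object)),
        if (length(sizes)) paste(range(sizes), collapse = "-") else "-"))
})

setMethod("show", "PairLabelSet", function(object) {
    cat(sprintf("PairLabelSet: %d positive, %d negative, %d excluded pairs\n",
        sum(object@labeled$positive), sum(!object@labeled$positive),
        nrow(object@excluded)))
})

setMethod("show", "RpcaResult", function(object) {
    cat(sprintf(
        "RpcaResult: %d x %d, lambda = %.5g, %d iterations, %sconverged (residual %.3g)\n",
        nrow(object@lowRank), ncol(object@lowRank), object@lambda,
        object@iterations, if (object@converged) "" else "NOT ",
        object@finalResidual))
})
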