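#' @import methods
NULL

.ORIENTATIONS <- c("genes_as_rows", "samples_as_rows")

#' GeneEffectMatrix: a gene x condition fitness matrix
#'
#' Container for a real-valued gene effect matrix (CERES/Chronos-like
#' dependency scores, or log-expression) together with gene and sample
#' identifiers and an explicit orientation flag. Gene and sample ids are
#' carried as the dimnames of the `values` slot; which axis holds genes is
#' recorded in `orientation` so that transposes are always explicit.
#'
#' @slot values numeric matrix; `NA` marks missing entries.
#' @slot orientation either `"genes_as_rows"` or `"samples_as_rows"`.
#' @aliases GeneEffectMatrix-class
#' @exportClass GeneEffectMatrix
setClass("GeneEffectMatrix",
    representation(values = "matrix", orientation = "character"),
    prototype(values = matrix(numeric(0), 0, 0), orientation = "genes_as_rows"))

setValidity("GeneEffectMatrix", function(object) {
    msg <- character(0)
    if (!is.numeric(object@values))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (length(object@orientation) != 1L ||
        !object@orientation %in% .ORIENTATIONS)
        msg <- c(msg, sprintf("'orientation' must be one of %s",
                              paste(.ORIENTATIONS, collapse = ", ")))
    dn <- dimnames(object@values)
    if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
        msg <- c(msg, "'values' must carry row and column names (gene/sample ids)")
    else {
        if (anyDuplicated(dn[[1L]])) msg <- c(msg, "row ids are not unique")
        if (anyDuplicated(dn[[2L]])) msg <- c(msg, "column ids are not unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneEffectMatrix
#'
#' @param values numeric matrix with dimnames.
#' @param orientation which axis carries genes: `"genes_as_rows"` (canonical
#'   in-memory layout) or `"samples_as_rows"` (the DepMap-style on-disk
#'   layout).
#' @return A [GeneEffectMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' gem <- GeneEffectMatrix(m)
#' geneIds(gem)
#' @export
GeneEffectMatrix <- function(values, orientation = "genes_as_rows") {
    new("GeneEffectMatrix", values = values, orientation = orientation)
}

#' NormalizedLayer: a normalized copy of a GeneEffectMatrix
#'
#' A [GeneEffectMatrix-class] plus provenance: which normalization produced
#' it (`pca`, `rpca`, `rpca_reconstructed`, `ae`, `ae_reconstructed` or
#' `none`) and at which hyperparameter value (number of removed components
#' n, the lambda multiplier f, or the latent-space size LS).
#'
#' @slot method character, the normalization method tag.
#' @slot hyperparameter numeric, the method's hyperparameter value.
#' @slot sourceHash character, opaque digest of the source matrix.
#' @aliases NormalizedLayer-class
#' @exportClass NormalizedLayer
setClass("NormalizedLayer", contains = "GeneEffectMatrix",
    representation(method = "character", hyperparameter = "numeric",
                   sourceHash = "character"),
    prototype(method = "none", hyperparameter = NA_real_, sourceHash = ""))

setValidity("NormalizedLayer", function(object) {
    ok <- c("pca", "rpca", "rpca_reconstructed", "ae", "ae_reconstructed", "none")
    if (!object@method %in% ok)
        sprintf("'method' must be one of %s", paste(ok, collapse = ", "))
    else TRUE
})

NormalizedLayer <- function(values, source, method, hyperparameter) {
    new("NormalizedLayer", values = values, orientation = orientation(source),
        method = method, hyperparameter = as.numeric(hyperparameter),
        sourceHash = .matrixHash(scoreMatrix(source)))
}

#' PcaModel: loadings of a fitted principal component analysis
#'
#' @slot loadings variables x components orthonormal loading matrix, ordered
#'   by decreasing explained variance.
#' @slot centers,scales per-variable centering/scaling constants used before
#'   the decomposition (length 0 when centering/scaling was off).
#' @slot sdev per-component standard deviations (square roots of the
#'   explained variances), non-increasing.
#' @aliases PcaModel-class
#' @exportClass PcaModel
setClass("PcaModel",
    representation(loadings = "matrix", centers = "numeric",
                   scales = "numeric", sdev = "numeric"))

setValidity("PcaModel", function(object) {
    L <- object@loadings
    if (ncol(L) > 0) {
        g <- crossprod(L)
        if (max(abs(g - diag(ncol(L)))) > 1e-8)
            return("loading columns are not orthonormal (tolerance 1e-8)")
        if (is.unsorted(rev(object@sdev), strictly = FALSE) &&
            any(diff(object@sdev) > 1e-10))
            return("explained variances must be non-increasing")
    }
    TRUE
})

#' RpcaResult: a low-rank + sparse decomposition
#'
#' Result of principal component pursuit: `X = L + S` with `L` low rank and
#' `S` sparse, obtained by minimizing `||L||_* + lambda * ||S||_1`.
#'
#' @slot lowRank,sparse numeric matrices with `lowRank + sparse ~ X`.
#' @slot lambda the sparsity weight used.
#' @slot iterations number of ALM iterations performed.
#' @slot converged whether the relative Frobenius residual fell below the
#'   tolerance before `maxIter`.
#' @slot finalResidual final `||X - L - S||_F / ||X||_F`.
#' @aliases RpcaResult-class
#' @exportClass RpcaResult
setClass("RpcaResult",
    representation(lowRank = "matrix", sparse = "matrix", lambda = "numeric",
                   iterations = "integer", converged = "logical",
                   finalResidual = "numeric"))

setValidity("RpcaResult", function(object) {
    if (!isTRUE(object@lambda > 0)) return("'lambda' must be positive")
    if (!identical(dim(object@lowRank), dim(object@sparse)))
        return("lowRank and sparse dimensions differ")
    TRUE
})

#' SimilarityNetwork: a symmetric Pearson-correlation network
#'
#' @slot weights symmetric numeric matrix in `[-1, 1]` with unit diagonal;
#'   dimnames carry the node ids.
#' @slot kind `"gene"` or `"cell_line"`.
#' @aliases SimilarityNetwork-class
#' @exportClass SimilarityNetwork
setClass("SimilarityNetwork",
    representation(weights = "matrix", kind = "character"),
    prototype(kind = "gene"))

.checkSquareNamed <- function(w) {
    msg <- character(0)
    if (nrow(w) != ncol(w)) msg <- c(msg, "weight matrix must be square")
    dn <- dimnames(w)
    if (is.null(dn) || is.null(dn[[1L]]) || !identical(dn[[1L]], dn[[2L]]))
        msg <- c(msg, "weight matrix must have identical row/column node ids")
    else if (anyDuplicated(dn[[1L]])) msg <- c(msg, "node ids are not unique")
    if (length(w) && !all(is.finite(w))) msg <- c(msg, "weights must be finite")
    msg
}

setValidity("SimilarityNetwork", function(object) {
    w <- object@weights
    msg <- .checkSquareNamed(w)
    if (!object@kind %in% c("gene", "cell_line"))
        msg <- c(msg, "'kind' must be 'gene' or 'cell_line'")
    if (!length(msg) && length(w)) {
        if (max(abs(w - t(w))) > 1e-12) msg <- c(msg, "weights not symmetric")
        if (max(abs(diag(w) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
        if (min(w) < -1 - 1e-12 || max(w) > 1 + 1e-12)
            msg <- c(msg, "weights outside [-1, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' AffinityNetwork: scaled exponential kernel affinities
#'
#' @slot weights symmetric nonnegative matrix with strictly positive
#'   diagonal.
#' @slot sigma kernel bandwidth multiplier.
#' @slot kNeighbors neighborhood size used for the local scale.
#' @aliases AffinityNetwork-class
#' @exportClass AffinityNetwork
setClass("AffinityNetwork",
    representation(weights = "matrix", sigma = "numeric",
                   kNeighbors = "integer"))

setValidity("AffinityNetwork", function(object) {
    w <- object@weights
    msg <- .checkSquareNamed(w)
    if (!length(msg) && length(w)) {
        if (max(abs(w - t(w))) > 1e-10) msg <- c(msg, "weights not symmetric")
        if (any(diag(w) <= 0)) msg <- c(msg, "diagonal must be strictly positive")
        if (min(w) < 0) msg <- c(msg, "affinities must be nonnegative")
    }
    if (length(msg)) msg else TRUE
})

#' FusedNetwork: the onion-normalized network
#'
#' Output of similarity network fusion (or max-weight fusion) over a stack
#' of per-hyperparameter layers.
#'
#' @slot weights symmetric nonnegative matrix.
#' @slot provenance character vector describing the fused layers.
#' @slot config list of fusion settings (sigma, kNeighbors, iterations, ...).
#' @aliases FusedNetwork-class
#' @exportClass FusedNetwork
setClass("FusedNetwork",
    representation(weights = "matrix", provenance = "character",
                   config = "list"))

setValidity("FusedNetwork", function(object) {
    w <- object@weights
    msg <- .checkSquareNamed(w)
    if (!length(msg) && length(w)) {
        if (max(abs(w - t(w))) > 1e-10) msg <- c(msg, "weights not symmetric")
        if (min(w) < 0) msg <- c(msg, "weights must be nonnegative")
    }
    if (length(msg)) msg else TRUE
})

#' CoAnnotationStandard: complex -> gene-set co-annotation standard
#'
#' A CORUM-like gold standard: a named list mapping complex ids to gene-id
#' character vectors. Genes may belong to several complexes; every complex
#' has at least two members.
#'
#' @slot complexes named list of character vectors.
#' @aliases CoAnnotationStandard-class
#' @exportClass CoAnnotationStandard
setClass("CoAnnotationStandard", representation(complexes = "list"))

setValidity("CoAnnotationStandard", function(object) {
    cx <- object@complexes
    if (length(cx)) {
        if (is.null(names(cx)) || anyDuplicated(names(cx)))
            return("complexes must have unique names")
        if (!all(vapply(cx, is.character, logical(1))))
            return("complex members must be character vectors")
        if (any(vapply(cx, function(g) length(unique(g)), integer(1)) < 2L))
            return("every complex needs >= 2 distinct genes")
    }
    TRUE
})

#' @rdname CoAnnotationStandard-class
#' @param complexes named list of character gene-id vectors.
#' @export
CoAnnotationStandard <- function(complexes) {
    new("CoAnnotationStandard",
        complexes = lapply(complexes, function(g) unique(as.character(g))))
}

#' PairLabelSet: labeled unordered gene pairs
#'
#' Positive (co-complex), negative (co-annotated universe, no shared
#' complex) and excluded (both members on the exclusion list) unordered
#' gene pairs. Pairs are stored with `geneA < geneB`; the three sets are
#' disjoint and excluded pairs participate in no benchmark quantity.
#'
#' @slot labeled data.frame with columns `geneA`, `geneB`, `positive`
#'   (logical).
#' @slot excluded data.frame with columns `geneA`, `geneB`.
#' @aliases PairLabelSet-class
#' @exportClass PairLabelSet
setClass("PairLabelSet",
    representation(labeled = "data.frame", excluded = "data.frame"))

setValidity("PairLabelSet", function(object) {
    lb <- object@labeled
    if (!all(c("geneA", "geneB", "positive") %in% names(lb)))
        return("'labeled' needs columns geneA, geneB, positive")
    if (nrow(lb) && any(lb$geneA >= lb$geneB))
        return("pairs must be stored with geneA < geneB and no self-pairs")
    TRUE
})
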