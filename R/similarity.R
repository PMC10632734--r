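#' Pearson similarity network from profiles
#'
#' Builds a gene-gene (or cell-line-cell-line) network whose edge weights
#' are Pearson correlation coefficients between profiles; the diagonal is
#' set to 1. Zero-variance profiles cannot be correlated and are dropped
#' with a warning; more than 10% dropped is an error.
#'
#' @param x a [GeneEffectMatrix-class] / [NormalizedLayer-class], or a
#'   numeric matrix with one profile per row.
#' @param kind node type of the network: `"gene"` (profiles = gene rows,
#'   default) or `"cell_line"` (profiles = sample rows).
#' @return A [SimilarityNetwork-class].
#' @export
pccNetwork <- function(x, kind = c("gene", "cell_line")) {
    kind <- match.arg(kind)
    m <- if (is.matrix(x)) x else
        scoreMatrix(x, if (kind == "gene") "genes_as_rows" else "samples_as_rows")
    .assertNoMissing(m, "profile matrix")
    if (ncol(m) < 3L)
        stop("need >= 3 conditions per profile for correlation", call. = FALSE)
    v <- apply(m, 1L, stats::var)
    if (any(v == 0)) {
        nBad <- sum(v == 0)
        if (nBad > 0.1 * nrow(m))
            stop(nBad, " zero-variance profiles (> 10% of nodes)",
                 call. = FALSE)
        warning("dropping ", nBad, " zero-variance profile(s): ",
                paste(utils::head(rownames(m)[v == 0], 5L), collapse = ", "),
                call. = FALSE)
        m <- m[v > 0, , drop = FALSE]
    }
    w <- stats::cor(t(m))
    w[w > 1] <- 1; w[w < -1] <- -1
    w <- (w + t(w)) / 2
    diag(w) <- 1
    new("SimilarityNetwork", weights = w, kind = kind)
}

#' Convert correlations to distances
#'
#' `d = 1 - w`: correlation 1 maps to distance 0 and correlation -1 to
#' distance 2; the diagonal becomes 0 and symmetry is preserved.
#'
#' @param s a [SimilarityNetwork-class] or symmetric correlation matrix.
#' @return A symmetric distance matrix in `[0, 2]`.
#' @export
toDistance <- function(s) {
    w <- if (is.matrix(s)) s else weightMatrix(s)
    1 - w
}

#' Scaled exponential similarity kernel
#'
#' Converts a distance matrix into an affinity matrix with a locally scaled
#' Gaussian kernel (the SNF `affinityMatrix` convention): for nodes `i, j`
#' the local scale is `eps_ij = (mean_i + mean_j)/3 * 2/2 + d_ij/3` where
#' `mean_i` is the mean distance from `i` to its `k` nearest neighbours
#' (self excluded), and the affinity is the Gaussian density of `d_ij` at
#' standard deviation `sigma * eps_ij` (including the normalizing
#' prefactor). The result is symmetrized by averaging. The scale is floored
#' to avoid division by zero on coincident points; nearest-neighbour ties
#' are resolved by node order.
#'
#' @param dist symmetric nonnegative distance matrix with node ids as
#'   dimnames (e.g. from [toDistance()]).
#' @param k neighbourhood size for the local scale (`0 < k <` number of
#'   nodes).
#' @param sigma bandwidth multiplier (> 0).
#' @return An [AffinityNetwork-class].
#' @export
affinityNetwork <- function(dist, k = 5L, sigma = 0.5) {
    stopifnot(is.matrix(dist))
    n <- nrow(dist)
    if (!(k >= 1L && k < n)) stop("need 1 <= k < number of nodes", call. = FALSE)
    if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
    D <- (dist + t(dist)) / 2
    diag(D) <- 0
    # mean distance to the k nearest neighbours of each node, self excluded
    means <- apply(D, 2L, function(col) {
        mean(sort(col, method = "radix")[seq_len(k) + 1L])
    }) + .Machine$double.eps
    eps <- (outer(means, means, `+`)) / 3 + D / 3 + .Machine$double.eps
    eps[eps <= .Machine$double.eps] <- .Machine$double.eps
    W <- stats::dnorm(D, mean = 0, sd = sigma * eps)
    W <- (W + t(W)) / 2
    dimnames(W) <- dimnames(dist)
    new("AffinityNetwork", weights = W, sigma = sigma,
        kNeighbors = as.integer(k))
}
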