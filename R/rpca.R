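#' Suggested sparsity weight for principal component pursuit
#'
#' The standard choice `lambda = f / sqrt(max(r, c))` for an `r x c` matrix,
#' with multiplier `f` (the onion grid dials `f = 0.7, ..., 1.3`; `f = 1`
#' gives the theoretically suggested value).
#'
#' @param r,c matrix dimensions (positive integers).
#' @param f positive multiplier.
#' @return `f / sqrt(max(r, c))`.
#' @examples
#' defaultLambda(4, 9)      # 1/3
#' defaultLambda(18119, 769)
#' @export
defaultLambda <- function(r, c, f = 1) {
    if (!all(r >= 1, c >= 1, f > 0))
        stop("need r, c >= 1 and f > 0", call. = FALSE)
    f / sqrt(max(r, c))
}

# Singular value thresholding: the proximal operator of the nuclear norm.
.svt <- function(M, tau) {
    s <- svd(M)
    d <- pmax(s$d - tau, 0)
    keep <- d > 0
    if (!any(keep))
        return(list(L = matrix(0, nrow(M), ncol(M)), rank = 0L, d = d))
    L <- s$u[, keep, drop = FALSE] %*%
        (d[keep] * t(s$v[, keep, drop = FALSE]))
    list(L = L, rank = sum(keep), d = d)
}

.softThreshold <- function(M, tau) sign(M) * pmax(abs(M) - tau, 0)

#' Robust PCA by inexact augmented Lagrange multipliers
#'
#' Decomposes `X` into a low-rank component `L` and a sparse component `S`
#' (`X = L + S`) by principal component pursuit: minimize
#' `||L||_* + lambda ||S||_1` subject to `X = L + S`. The solver is the
#' augmented-Lagrange-multiplier iteration — singular value thresholding on
#' `L`, elementwise soft thresholding on `S`, dual update on the
#' multiplier — at constant penalty `mu = r c / (4 ||X||_1)`, terminating
#' at relative Frobenius residual `tol`. The solver is fully
#' deterministic.
#'
#' @param x a [GeneEffectMatrix-class] or numeric matrix without missing
#'   values.
#' @param lambda sparsity weight; default [defaultLambda()] with the input's
#'   own dimensions.
#' @param tol relative Frobenius termination tolerance (default `1e-7`).
#' @param maxIter iteration cap (default 5000).
#' @param orientation layout on which to decompose when `x` is a
#'   [GeneEffectMatrix-class]: `"genes_as_rows"` for gene networks (rows =
#'   genes), `"samples_as_rows"` for the cell-line network variant. Never
#'   inferred.
#' @return An [RpcaResult-class].
#' @references Candes, Li, Ma & Wright (2011) Robust principal component
#'   analysis? JACM 58(3). Lin, Chen & Ma (2010) The augmented Lagrange
#'   multiplier method for exact recovery of corrupted low-rank matrices.
#' @export
rpcaDecompose <- function(x, lambda = NULL, tol = 1e-7, maxIter = 5000L,
                          orientation = "genes_as_rows") {
    X <- if (is.matrix(x)) x else scoreMatrix(x, orientation)
    if (anyNA(X) || !all(is.finite(X)))
        stop("non-finite entries; impute before RPCA", call. = FALSE)
    if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
    r <- nrow(X); c <- ncol(X)
    if (is.null(lambda)) lambda <- defaultLambda(r, c)
    if (lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
    normX <- sqrt(sum(X^2))
    if (normX == 0) {
        Z <- X * 0
        return(new("RpcaResult", lowRank = Z, sparse = Z, lambda = lambda,
                   iterations = 0L, converged = TRUE, finalResidual = 0))
    }
    l1 <- sum(abs(X))
    # constant penalty, the augmented-Lagrange schedule of the reference
    # principal-component-pursuit implementation: growing mu collapses the
    # singular-value threshold and loses optimality
    mu <- r * c / (4 * l1)
    S <- matrix(0, r, c)
    Y <- matrix(0, r, c)
    L <- matrix(0, r, c)
    converged <- FALSE
    resid <- Inf
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        L <- .svt(X - S + Y / mu, 1 / mu)$L
        S <- .softThreshold(X - L + Y / mu, lambda / mu)
        R <- X - L - S
        resid <- sqrt(sum(R^2)) / normX
        if (resid < tol) { converged <- TRUE; break }
        Y <- Y + mu * R
    }
    dimnames(L) <- dimnames(S) <- dimnames(X)
    new("RpcaResult", lowRank = L, sparse = S, lambda = lambda,
        iterations = iter, converged = converged, finalResidual = resid)
}

#' RPCA-normalize a gene effect matrix
#'
#' Runs principal component pursuit at `lambda = f / sqrt(max(r, c))` using
#' the input's own dimensions. The sparse component `S` is the
#' RPCA-normalized layer (the dominant low-rank signal removed) and the
#' low-rank component `L` is the RPCA-reconstructed layer. Larger `f`
#' (larger lambda) makes sparsity more expensive, so the low-rank
#' component absorbs more dimensions.
#'
#' @inheritParams rpcaDecompose
#' @param f lambda multiplier (the onion grid is `f = 0.7, ..., 1.3`).
#' @return A list with elements `normalized` (`method = "rpca"`,
#'   `hyperparameter = f`), `reconstructed`
#'   (`method = "rpca_reconstructed"`) and `result` (the
#'   [RpcaResult-class]).
#' @export
rpcaNormalize <- function(x, f = 1, tol = 1e-7, maxIter = 5000L,
                          orientation = "genes_as_rows") {
    stopifnot(is(x, "GeneEffectMatrix"))
    X <- scoreMatrix(x, orientation)
    lambda <- defaultLambda(nrow(X), ncol(X), f)
    res <- rpcaDecompose(X, lambda = lambda, tol = tol, maxIter = maxIter)
    back <- function(m) if (orientation == orientation(x)) m else t(m)
    list(normalized = NormalizedLayer(back(res@sparse), x, "rpca", f),
         reconstructed = NormalizedLayer(back(res@lowRank), x,
                                         "rpca_reconstructed", f),
         result = res)
}
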