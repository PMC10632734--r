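#' Fit a principal component analysis of a gene effect matrix
#'
#' SVD-based PCA with genes as variables (columns of the samples-as-rows
#' layout), equivalent to `prcomp(t(genes x samples), center, scale.)`.
#' Loadings are returned in decreasing order of explained variance with a
#' fixed sign convention (largest-magnitude element of each loading made
#' positive), which stabilizes serialization; reconstructions are
#' sign-invariant.
#'
#' @param x a [GeneEffectMatrix-class] with no missing values.
#' @param center,scale whether to center/scale each gene before the
#'   decomposition (both default `TRUE`, the convention for dependency-map
#'   normalization).
#' @return A [PcaModel-class].
#' @export
fitPca <- function(x, center = TRUE, scale = TRUE) {
    m <- scoreMatrix(x, "samples_as_rows")
    .assertNoMissing(m, "gene effect matrix")
    if (scale) {
        v <- apply(m, 2L, stats::sd)
        if (any(v == 0))
            stop("zero-variance variable(s) with scale = TRUE: ",
                 paste(colnames(m)[v == 0], collapse = ", "), call. = FALSE)
    }
    p <- stats::prcomp(m, center = center, scale. = scale)
    L <- p$rotation
    flip <- vapply(seq_len(ncol(L)), function(j) {
        i <- which.max(abs(L[, j]))
        L[i, j] < 0
    }, logical(1))
    L[, flip] <- -L[, flip]
    new("PcaModel", loadings = L,
        centers = if (is.numeric(p$center)) as.numeric(p$center) else numeric(0),
        scales = if (is.numeric(p$scale)) as.numeric(p$scale) else numeric(0),
        sdev = p$sdev)
}

# The working matrix in the coordinate system the model was fit in
# (samples x genes, centered/scaled per the fit flags).
.pcaWorking <- function(x, model) {
    m <- scoreMatrix(x, "samples_as_rows")
    .assertNoMissing(m, "gene effect matrix")
    if (length(model@centers)) m <- sweep(m, 2L, model@centers, `-`)
    if (length(model@scales)) m <- sweep(m, 2L, model@scales, `/`)
    m
}

#' Reconstruct a matrix from its first n principal components
#'
#' Projects the (centered/scaled, per the fit flags) matrix onto the first
#' `n` loadings and maps back: `W %*% L_n %*% t(L_n)`. The reconstruction
#' lives in the standardized coordinate system; downstream Pearson
#' similarities are invariant to that choice.
#'
#' @param x a [GeneEffectMatrix-class].
#' @param model a [PcaModel-class] fitted on `x` (refit internally if
#'   `NULL`).
#' @param n number of leading components, `1 <= n <= ncol(loadings)`.
#' @return A [GeneEffectMatrix-class] (samples as rows) holding the rank-n
#'   reconstruction of the working matrix.
#' @export
pcaReconstruct <- function(x, n, model = NULL) {
    if (is.null(model)) model <- fitPca(x)
    nc <- ncol(model@loadings)
    if (!is.numeric(n) || length(n) != 1L || n < 1L || n > nc)
        stop("'n' must be in [1, ", nc, "]", call. = FALSE)
    n <- as.integer(n)
    W <- .pcaWorking(x, model)
    Ln <- model@loadings[, seq_len(n), drop = FALSE]
    R <- W %*% Ln %*% t(Ln)
    dimnames(R) <- dimnames(W)
    GeneEffectMatrix(R, "samples_as_rows")
}

#' PCA-normalize: subtract the strongest n components
#'
#' The normalized layer is the working (standardized) matrix minus its
#' rank-n PCA reconstruction — the residual after removing the `n`
#' strongest principal components.
#'
#' @inheritParams pcaReconstruct
#' @param center,scale passed to [fitPca()] when `model` is `NULL`.
#' @return A [NormalizedLayer-class] (`method = "pca"`,
#'   `hyperparameter = n`) in the orientation of `x`.
#' @export
pcaNormalize <- function(x, n, model = NULL, center = TRUE, scale = TRUE) {
    if (is.null(model)) model <- fitPca(x, center = center, scale = scale)
    W <- .pcaWorking(x, model)
    R <- scoreMatrix(pcaReconstruct(x, n, model), "samples_as_rows")
    res <- W - R
    if (orientation(x) == "genes_as_rows") res <- t(res)
    NormalizedLayer(res, x, "pca", n)
}

#' Default hyperparameter grids
#'
#' The per-method layer grids used for onion normalization: numbers of
#' removed principal components `n = 1, 3, ..., 19` (10 layers), lambda
#' multipliers `f = 0.7, ..., 1.3` (7 layers), and autoencoder latent sizes
#' `LS = 1, 2, 3, 4, 5, 10` (6 layers; the un-normalized network is fused
#' as a 7th layer for AEO).
#'
#' @param method `"pca"`, `"rpca"` or `"ae"`.
#' @return numeric vector of grid values.
#' @export
defaultGrid <- function(method = c("pca", "rpca", "ae")) {
    switch(match.arg(method),
           pca = seq(1, 19, by = 2),
           rpca = seq(0.7, 1.3, by = 0.1),
           ae = c(1, 2, 3, 4, 5, 10))
}
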