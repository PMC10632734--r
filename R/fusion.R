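#' Fusion settings for onion normalization
#'
#' Defaults follow the method-specific settings used for dependency-map
#' networks: `sigma = 0.3, k = 5` for PCO (PCA onion) and
#' `sigma = 0.5, k = 5` for RPCO and AEO, with 10 diffusion iterations; the
#' AEO stack additionally fuses the similarity network of the
#' un-normalized data as an extra layer.
#'
#' @param method normalization method the layers came from (sets the
#'   defaults); one of `"pca"`, `"rpca"`, `"ae"`.
#' @param sigma affinity-kernel bandwidth multiplier.
#' @param kNeighbors neighbourhood size for both the affinity kernel and
#'   the sparse diffusion kernel.
#' @param iterations number of cross-diffusion rounds (>= 1).
#' @param includeUnnormalizedLayer whether to append the raw-data layer
#'   (default `TRUE` only for `"ae"`).
#' @return A named list of settings (class `"FusionConfig"`).
#' @export
FusionConfig <- function(method = c("rpca", "pca", "ae"), sigma = NULL,
                         kNeighbors = 5L, iterations = 10L,
                         includeUnnormalizedLayer = NULL) {
    method <- match.arg(method)
    if (is.null(sigma)) sigma <- if (method == "pca") 0.3 else 0.5
    if (is.null(includeUnnormalizedLayer))
        includeUnnormalizedLayer <- method == "ae"
    stopifnot(iterations >= 1L, kNeighbors >= 1L, sigma > 0)
    structure(list(method = method, sigma = sigma,
                   kNeighbors = as.integer(kNeighbors),
                   iterations = as.integer(iterations),
                   includeUnnormalizedLayer = includeUnnormalizedLayer),
              class = c("FusionConfig", "list"))
}

# Align layers on a common node universe: identical sets pass through;
# otherwise the intersection (in the first layer's order) is used with a
# warning, and an intersection covering < 50% of the union is an error.
.alignLayers <- function(Ws) {
    ids <- rownames(Ws[[1L]])
    same <- all(vapply(Ws, function(W) identical(rownames(W), ids), logical(1)))
    if (same) return(Ws)
    common <- Reduce(intersect, lapply(Ws, rownames))
    un <- unique(unlist(lapply(Ws, rownames)))
    if (length(common) < 0.5 * length(un))
        stop("layer node sets share < 50% of their union", call. = FALSE)
    warning("layers differ in node sets; using their intersection (",
            length(common), " nodes)", call. = FALSE)
    common <- ids[ids %in% common]
    lapply(Ws, function(W) W[common, common, drop = FALSE])
}

# Row normalization with the 1/2-diagonal convention: off-diagonal entries
# sum to 1/2 per row, diagonal is 1/2 (so rows sum to 1).
.snfNormalize <- function(W) {
    rs <- rowSums(W) - diag(W)
    rs[rs == 0] <- 1
    P <- W / (2 * rs)
    diag(P) <- 0.5
    P
}

# Sparse kernel: keep each row's k largest entries (ties broken by node
# order), renormalized to sum 1 over the kept entries.
.snfDominateSet <- function(W, k) {
    n <- nrow(W)
    S <- matrix(0, n, n, dimnames = dimnames(W))
    for (i in seq_len(n)) {
        keep <- order(W[i, ], decreasing = TRUE)[seq_len(k)]
        v <- W[i, keep]
        S[i, keep] <- v / sum(v)
    }
    S
}

#' Similarity network fusion (cross-diffusion)
#'
#' Integrates affinity layers over an identical node set into one network
#' by iterative cross-diffusion: each layer's full kernel `P` (row
#' normalized with a 1/2 diagonal) is propagated through its sparse
#' k-nearest-neighbour kernel `S` against the average of the other layers,
#' `P_v <- S_v %*% mean(P_-v) %*% t(S_v)`, with symmetrization and
#' re-normalization after every round; the output is the symmetrized,
#' re-normalized mean of the final kernels.
#'
#' @param layers list of >= 2 [AffinityNetwork-class] objects (or square
#'   named affinity matrices) on identical node sets and ordering.
#' @param kNeighbors sparse-kernel neighbourhood size.
#' @param iterations number of diffusion rounds.
#' @param provenance optional character description of the layers.
#' @return A [FusedNetwork-class].
#' @references Wang et al (2014) Similarity network fusion for aggregating
#'   data types on a genomic scale. Nature Methods 11:333-337.
#' @export
snfFuse <- function(layers, kNeighbors = 5L, iterations = 10L,
                    provenance = NULL) {
    Ws <- lapply(layers, function(l) if (is.matrix(l)) l else weightMatrix(l))
    m <- length(Ws)
    if (m < 2L) stop("need >= 2 layers to fuse", call. = FALSE)
    Ws <- .alignLayers(Ws)
    ids <- rownames(Ws[[1L]])
    for (W in Ws)
        if (any(rowSums(W) == 0))
            stop("layer with an all-zero row", call. = FALSE)
    k <- as.integer(kNeighbors)
    if (!(k >= 1L && k < length(ids)))
        stop("need 1 <= kNeighbors < number of nodes", call. = FALSE)
    P <- lapply(Ws, function(W) {
        Pv <- .snfNormalize(W)
        (Pv + t(Pv)) / 2
    })
    S <- lapply(Ws, .snfDominateSet, k = k)
    for (it in seq_len(iterations)) {
        newP <- vector("list", m)
        for (v in seq_len(m)) {
            others <- Reduce(`+`, P[-v]) / (m - 1)
            newP[[v]] <- S[[v]] %*% others %*% t(S[[v]])
        }
        P <- lapply(newP, function(Pv) {
            Pv <- .snfNormalize(Pv)
            (Pv + t(Pv)) / 2
        })
    }
    W <- Reduce(`+`, P) / m
    W <- .snfNormalize(W)
    W <- (W + t(W)) / 2
    dimnames(W) <- list(ids, ids)
    if (is.null(provenance)) provenance <- paste0("layer", seq_len(m))
    new("FusedNetwork", weights = W, provenance = as.character(provenance),
        config = list(kNeighbors = k, iterations = as.integer(iterations)))
}

#' Max-weight fusion
#'
#' Elementwise maximum across similarity layers on one node set (the
#' integration used for the expression pathway).
#'
#' @param layers list of [SimilarityNetwork-class] objects or square named
#'   matrices on identical node sets.
#' @param provenance optional layer descriptions.
#' @return A [FusedNetwork-class].
#' @export
maxFuse <- function(layers, provenance = NULL) {
    Ws <- lapply(layers, function(l) if (is.matrix(l)) l else weightMatrix(l))
    Ws <- .alignLayers(Ws)
    W <- Reduce(pmax, Ws)
    if (is.null(provenance)) provenance <- paste0("layer", seq_along(Ws))
    new("FusedNetwork", weights = W, provenance = as.character(provenance),
        config = list(rule = "max"))
}

#' The onion pipeline: normalize, network, fuse
#'
#' Runs one normalization method over its hyperparameter grid, converts
#' every normalized layer to a Pearson similarity network, then a `1 - PCC`
#' distance, then a scaled exponential affinity, and fuses the affinity
#' stack by similarity network fusion. For `method = "ae"` with
#' `includeUnnormalizedLayer`, the raw data's similarity network is fused
#' as an extra layer through the identical kernel settings.
#'
#' @param x an imputed [GeneEffectMatrix-class].
#' @param method `"pca"`, `"rpca"` or `"ae"`.
#' @param grid hyperparameter grid; default [defaultGrid()] for the method.
#' @param config a [FusionConfig()].
#' @param kind node type of the networks (`"gene"` or `"cell_line"`); for
#'   `"cell_line"`, RPCA is applied in the samples-as-rows layout.
#' @param aeConfig an [AeConfig()] used when `method = "ae"` (its
#'   `latentSize` is overridden by each grid value).
#' @return A [FusedNetwork-class].
#' @export
onionPipeline <- function(x, method = c("pca", "rpca", "ae"), grid = NULL,
                          config = NULL, kind = c("gene", "cell_line"),
                          aeConfig = NULL) {
    method <- match.arg(method)
    kind <- match.arg(kind)
    if (is.null(grid)) grid <- defaultGrid(method)
    if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
    if (is.null(config)) config <- FusionConfig(method)
    layers <- normalizedLayers(x, method, grid, kind = kind,
                               aeConfig = aeConfig)
    prov <- sprintf("%s:%g", method, grid)
    if (isTRUE(config$includeUnnormalizedLayer)) {
        layers <- c(layers, list(NormalizedLayer(
            scoreMatrix(x, orientation(x)), x, "none", NA_real_)))
        prov <- c(prov, "none:raw")
    }
    aff <- lapply(layers, function(l) {
        s <- pccNetwork(l, kind = kind)
        affinityNetwork(toDistance(s), k = config$kNeighbors,
                        sigma = config$sigma)
    })
    fused <- snfFuse(aff, kNeighbors = config$kNeighbors,
                     iterations = config$iterations, provenance = prov)
    fused@config <- c(fused@config, list(sigma = config$sigma,
                                         method = method, grid = grid))
    fused
}

#' Normalized layers over a hyperparameter grid
#'
#' @inheritParams onionPipeline
#' @return list of [NormalizedLayer-class], one per grid value (the
#'   autoencoder grid trains one model per latent size).
#' @export
normalizedLayers <- function(x, method = c("pca", "rpca", "ae"), grid = NULL,
                             kind = c("gene", "cell_line"), aeConfig = NULL) {
    method <- match.arg(method)
    kind <- match.arg(kind)
    if (is.null(grid)) grid <- defaultGrid(method)
    rpcaOrient <- if (kind == "gene") "genes_as_rows" else "samples_as_rows"
    switch(method,
        pca = {
            model <- fitPca(x)
            lapply(grid, function(n) pcaNormalize(x, n, model = model))
        },
        rpca = lapply(grid, function(f)
            rpcaNormalize(x, f = f, orientation = rpcaOrient)$normalized),
        ae = {
            if (is.null(aeConfig)) aeConfig <- AeConfig()
            pre <- aePreprocess(x)
            lapply(grid, function(ls) {
                cfg <- aeConfig
                cfg$latentSize <- as.integer(ls)
                aeNormalize(pre, cfg, preprocessed = TRUE)$normalized
            })
        })
}
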