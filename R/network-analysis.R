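#' Top-N edge network
#'
#' The `N` highest-weight unordered node pairs of a network (the "top five,
#' ten or fifteen thousand edges" style cut). Ties at the boundary are
#' broken lexicographically by pair id, so `topEdges(net, N1)` is always a
#' prefix of `topEdges(net, N2)` for `N1 <= N2`.
#'
#' @param net network object or square named weight matrix.
#' @param N number of edges to keep (`1 <= N <=` number of pairs).
#' @return data.frame (`nodeA`, `nodeB`, `weight`) sorted by descending
#'   weight, with attribute `N`.
#' @export
topEdges <- function(net, N) {
    w <- .netMatrix(net)
    p <- .allPairs(rownames(w))
    if (N <= 0) stop("'N' must be positive", call. = FALSE)
    if (N > nrow(p))
        stop("'N' exceeds the number of unordered pairs (", nrow(p), ")",
             call. = FALSE)
    wt <- .pairWeights(w, p[, 1L], p[, 2L])
    o <- order(-wt, p[, 1L], p[, 2L])[seq_len(N)]
    out <- data.frame(nodeA = p[o, 1L], nodeB = p[o, 2L], weight = wt[o],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "N") <- as.integer(N)
    out
}

#' Connected components and summary statistics of an edge network
#'
#' Treats every connected component as a cluster and reports cluster
#' membership plus the counts mirrored in network characterizations:
#' number of clusters, number of genes present, and the mean degree
#' `2 |edges| / |nodes|` (average neighbours per gene).
#'
#' @param edges data.frame from [topEdges()] (columns `nodeA`, `nodeB`,
#'   `weight`).
#' @return list with `clusters` (list of node-id vectors, largest first)
#'   and `stats` (`nClusters`, `nGenes`, `nEdges`, `meanDegree`).
#' @export
componentsAndStats <- function(edges) {
    g <- igraph::graph_from_data_frame(
        edges[, c("nodeA", "nodeB", "weight")], directed = FALSE)
    comp <- igraph::components(g)
    clusters <- split(igraph::V(g)$name, comp$membership)
    clusters <- clusters[order(-lengths(clusters))]
    names(clusters) <- NULL
    nGenes <- igraph::vcount(g)
    nEdges <- igraph::ecount(g)
    list(clusters = clusters,
         stats = list(nClusters = as.integer(comp$no),
                      nGenes = as.integer(nGenes),
                      nEdges = as.integer(nEdges),
                      meanDegree = 2 * nEdges / nGenes))
}

#' Standardized within-cluster edge weight
#'
#' The mean pairwise weight inside a cluster, standardized against the
#' mean and standard deviation of all off-diagonal weights of the network:
#' `z = (mean_within - mean_all) / sd_all`. A cluster whose internal
#' weights sit at the global mean scores 0; denser clusters score higher.
#'
#' @param cluster character vector of >= 2 node ids.
#' @param net network object or square named weight matrix containing them.
#' @return The z-score (a single number).
#' @export
clusterZscore <- function(cluster, net) {
    w <- .netMatrix(net)
    cluster <- unique(cluster)
    if (length(cluster) < 2L)
        stop("cluster z-score is undefined for singletons", call. = FALSE)
    if (!all(cluster %in% rownames(w)))
        stop("cluster contains nodes absent from the network", call. = FALSE)
    off <- w[upper.tri(w)]
    sub <- w[cluster, cluster, drop = FALSE]
    within <- sub[upper.tri(sub)]
    (mean(within) - mean(off)) / stats::sd(off)
}
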