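# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (loops, enumeration, direct formulas) and never call the package
# path they check.

makeGem <- function(m, genesAsRows = TRUE, genes = NULL, samples = NULL) {
    if (!is.null(dimnames(m)) && is.null(genes) && is.null(samples))
        return(GeneEffectMatrix(m, if (genesAsRows) "genes_as_rows"
                                   else "samples_as_rows"))
    if (is.null(genes))
        genes <- sprintf("g%02d", seq_len(if (genesAsRows) nrow(m) else ncol(m)))
    if (is.null(samples))
        samples <- sprintf("s%02d", seq_len(if (genesAsRows) ncol(m) else nrow(m)))
    dimnames(m) <- if (genesAsRows) list(genes, samples) else list(samples, genes)
    GeneEffectMatrix(m, if (genesAsRows) "genes_as_rows" else "samples_as_rows")
}

randGem <- function(nGenes, nSamples, seed = 1) {
    set.seed(seed)
    makeGem(matrix(rnorm(nGenes * nSamples), nGenes, nSamples))
}

# symmetric positive affinity matrix fixture
randAffinity <- function(n, seed = 1, ids = sprintf("n%02d", seq_len(n))) {
    set.seed(seed)
    w <- matrix(runif(n * n, 0.05, 1), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 1
    dimnames(w) <- list(ids, ids)
    w
}

# ---- independent oracles ---------------------------------------------------

# scaled exponential kernel, evaluated entry by entry from the formula
oracleAffinity <- function(D, k, sigma) {
    n <- nrow(D)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    mu <- numeric(n)
    for (i in seq_len(n)) {
        others <- sort(D[-i, i])
        mu[i] <- mean(others[seq_len(k)]) + .Machine$double.eps
    }
    W <- matrix(0, n, n, dimnames = dimnames(D))
    for (i in seq_len(n))
        for (j in seq_len(n)) {
            eps <- (mu[i] + mu[j] + D[i, j]) / 3 + .Machine$double.eps
            W[i, j] <- dnorm(D[i, j], 0, sigma * eps)
        }
    (W + t(W)) / 2
}

# literal loop-based SNF cross-diffusion reference
oracleSnf <- function(Ws, k, iterations) {
    n <- nrow(Ws[[1]])
    m <- length(Ws)
    normalize <- function(W) {
        P <- matrix(0, n, n)
        for (i in seq_len(n)) {
            rs <- sum(W[i, ]) - W[i, i]
            if (rs == 0) rs <- 1
            for (j in seq_len(n)) P[i, j] <- W[i, j] / (2 * rs)
            P[i, i] <- 0.5
        }
        P
    }
    dominate <- function(W) {
        S <- matrix(0, n, n)
        for (i in seq_len(n)) {
            nb <- order(W[i, ], decreasing = TRUE)[seq_len(k)]
            S[i, nb] <- W[i, nb] / sum(W[i, nb])
        }
        S
    }
    P <- lapply(Ws, function(W) {
        Pv <- normalize(W); (Pv + t(Pv)) / 2
    })
    S <- lapply(Ws, dominate)
    for (it in seq_len(iterations)) {
        newP <- vector("list", m)
        for (v in seq_len(m)) {
            avg <- matrix(0, n, n)
            for (u in seq_len(m)) if (u != v) avg <- avg + P[[u]]
            avg <- avg / (m - 1)
            newP[[v]] <- S[[v]] %*% avg %*% t(S[[v]])
        }
        for (v in seq_len(m)) {
            Pv <- normalize(newP[[v]])
            P[[v]] <- (Pv + t(Pv)) / 2
        }
    }
    W <- Reduce(`+`, P) / m
    W <- normalize(W)
    W <- (W + t(W)) / 2
    dimnames(W) <- dimnames(Ws[[1]])
    W
}

# average precision by direct enumeration over a ranked logical vector
oracleAveragePrecision <- function(positive) {
    tp <- 0; s <- 0
    for (i in seq_along(positive)) {
        if (positive[i]) {
            tp <- tp + 1
            s <- s + tp / i
        }
    }
    s / sum(positive)
}

# named dense network from an explicit edge weight list (others 0)
toyNetwork <- function(ids, edges) {
    n <- length(ids)
    w <- matrix(0, n, n, dimnames = list(ids, ids))
    for (e in edges) {
        w[e[[1]], e[[2]]] <- e[[3]]
        w[e[[2]], e[[1]]] <- e[[3]]
    }
    diag(w) <- 1
    w
}
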