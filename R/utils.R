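# Internal helpers shared across modules.

# Cheap deterministic digest of a numeric matrix; provenance only, not
# cryptographic.
.matrixHash <- function(m) {
    v <- as.numeric(m)
    v <- v[is.finite(v)]
    s <- if (length(v)) sum(v) + sum(v * seq_along(v) %% 97) else 0
    sprintf("%dx%d:%.10e", nrow(m), ncol(m), s)
}

.assertNoMissing <- function(m, what = "matrix") {
    if (anyNA(m))
        stop(what, " contains missing values; impute first (imputeGeneMean)",
             call. = FALSE)
    if (!all(is.finite(m)))
        stop(what, " contains non-finite values", call. = FALSE)
    invisible(m)
}

# Canonical unordered pair key "a|b" with a < b.
.pairKey <- function(a, b) {
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    paste(a, b, sep = "|")
}

# All unordered pairs of a character vector, as a two-column matrix with
# geneA < geneB, in lexicographic order.
.allPairs <- function(ids) {
    ids <- sort(unique(ids))
    n <- length(ids)
    if (n < 2L)
        return(matrix(character(0), 0, 2,
                      dimnames = list(NULL, c("geneA", "geneB"))))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cbind(geneA = ids[idx[, 1L]], geneB = ids[idx[, 2L]])
}

# Extract edge weights for given unordered pairs from a square named matrix.
.pairWeights <- function(w, geneA, geneB) {
    w[cbind(match(geneA, rownames(w)), match(geneB, colnames(w)))]
}
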