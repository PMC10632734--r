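#' Replace missing scores by gene-wise means
#'
#' Every missing entry of a gene's profile is replaced by the mean of that
#' gene's observed values; observed entries are untouched, so the operation
#' is idempotent. A gene with no observed value at all is an error.
#'
#' @param x a [GeneEffectMatrix-class] (any orientation).
#' @return A [GeneEffectMatrix-class] with no missing values, in the input
#'   orientation.
#' @export
imputeGeneMean <- function(x) {
    stopifnot(is(x, "GeneEffectMatrix"))
    m <- scoreMatrix(x, "genes_as_rows")
    nObs <- rowSums(!is.na(m))
    if (any(nObs == 0L))
        stop("gene(s) with all entries missing: ",
             paste(rownames(m)[nObs == 0L], collapse = ", "), call. = FALSE)
    if (anyNA(m)) {
        mu <- rowMeans(m, na.rm = TRUE)
        idx <- which(is.na(m), arr.ind = TRUE)
        m[idx] <- mu[idx[, 1L]]
    }
    if (orientation(x) == "samples_as_rows") m <- t(m)
    GeneEffectMatrix(m, orientation(x))
}

#' Autoencoder preprocessing chain
#'
#' Prepares fitness profiles for autoencoder training: (1) each gene profile
#' is standardized to mean 0, sd 1; (2) z-scores beyond +/- 4 are clipped to
#' +/- 4; (3) the whole matrix is min-max scaled onto `[-1, 1]`. Requires an
#' already-imputed matrix; a constant profile (sd = 0) is an error.
#'
#' Standardization operates on gene profiles (the autoencoder consumes one
#' gene profile per sample); adding a per-gene constant to the input
#' therefore leaves the output unchanged.
#'
#' @param x a [GeneEffectMatrix-class] with no missing values.
#' @param clip absolute z-score clip point (default 4).
#' @return A [GeneEffectMatrix-class] in `genes_as_rows` orientation with
#'   values in `[-1, 1]`.
#' @export
aePreprocess <- function(x, clip = 4) {
    stopifnot(is(x, "GeneEffectMatrix"))
    m <- scoreMatrix(x, "genes_as_rows")
    .assertNoMissing(m, "gene effect matrix")
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
        stop("constant gene profile(s), sd = 0: ",
             paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    z <- (m - rowMeans(m)) / sds
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    lo <- min(z); hi <- max(z)
    if (hi > lo) z <- 2 * (z - lo) / (hi - lo) - 1 else z[] <- 0
    GeneEffectMatrix(z, "genes_as_rows")
}

#' Read a Cell Ranger MTX triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' `.gz`-compressed, and `genes.tsv` is accepted for the features file).
#' Counts must be nonnegative.
#'
#' @param dir directory holding the triplet.
#' @return A [GeneEffectMatrix-class] (genes as rows, dense) of counts.
#' @export
readCountsMtx <- function(dir) {
    find <- function(stem) {
        for (f in c(file.path(dir, paste0(stem, ".gz")), file.path(dir, stem)))
            if (file.exists(f)) return(f)
        stop("missing '", stem, "[.gz]' in ", dir, call. = FALSE)
    }
    mtx <- tryCatch(find("matrix.mtx"), error = function(e) e)
    if (inherits(mtx, "error")) stop(conditionMessage(mtx), call. = FALSE)
    feat <- tryCatch(find("features.tsv"),
                     error = function(e) find("genes.tsv"))
    bc <- find("barcodes.tsv")
    readTsvCol <- function(f, col = 1L) {
        # read.table handles gzip transparently via file()
        df <- utils::read.table(f, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
        df[[min(col, ncol(df))]]
    }
    readMtx <- function(f) {
        if (grepl("\\.gz$", f)) {
            tmp <- tempfile(fileext = ".mtx")
            on.exit(unlink(tmp))
            writeLines(readLines(gzfile(f)), tmp)
            f <- tmp
        }
        as.matrix(Matrix::readMM(f))
    }
    m <- readMtx(mtx)
    if (min(m) < 0) stop("negative counts in ", mtx, call. = FALSE)
    genes <- readTsvCol(feat, 2L)  # prefer the symbol column
    if (anyDuplicated(genes)) genes <- make.unique(genes)
    cells <- readTsvCol(bc, 1L)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
        stop("matrix dimensions do not match features/barcodes", call. = FALSE)
    dimnames(m) <- list(genes, cells)
    GeneEffectMatrix(m, "genes_as_rows")
}

#' Filter an expression count matrix
#'
#' Single-cell quality filters: genes whose number of cells with non-zero
#' counts is less than or equal to `minNonzeroCells` are removed; cells with
#' a number of detected genes `<= minGenes` or `>= maxGenes`, or whose
#' percentage of counts mapping to mitochondrial genes (symbols starting
#' with `mitoPrefix`) is not below `maxMitoPct`, are removed. The gene
#' filter is computed on the input matrix and the cell filters on the
#' gene-filtered matrix, in one pass.
#'
#' @param x a counts [GeneEffectMatrix-class] (genes as rows).
#' @param minNonzeroCells gene kept only if detected in more than this many
#'   cells (default 50).
#' @param minGenes,maxGenes cell kept only if its number of detected genes
#'   is strictly between these bounds (defaults 100 and 4500).
#' @param maxMitoPct cell kept only if its mitochondrial read percentage is
#'   strictly below this (default 7).
#' @param mitoPrefix gene-symbol prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return The filtered [GeneEffectMatrix-class].
#' @export
filterExpression <- function(x, minNonzeroCells = 50, minGenes = 100,
                             maxGenes = 4500, maxMitoPct = 7,
                             mitoPrefix = "MT-") {
    m <- scoreMatrix(x, "genes_as_rows")
    if (min(m, na.rm = TRUE) < 0) stop("negative counts", call. = FALSE)
    mitoAll <- startsWith(rownames(m), mitoPrefix)
    mitoPct <- 100 * colSums(m[mitoAll, , drop = FALSE]) /
        pmax(colSums(m), .Machine$double.eps)
    keepGene <- rowSums(m > 0) > minNonzeroCells
    mg <- m[keepGene, , drop = FALSE]
    nFeat <- colSums(mg > 0)
    keepCell <- nFeat > minGenes & nFeat < maxGenes & mitoPct < maxMitoPct
    if (!any(keepGene)) stop("all genes removed by the cell-count filter",
                             call. = FALSE)
    if (!any(keepCell)) stop("all cells removed by the quality filters",
                             call. = FALSE)
    GeneEffectMatrix(mg[, keepCell, drop = FALSE], "genes_as_rows")
}

#' Log-normalize a count matrix
#'
#' Per cell, a count `x` in a cell with total counts `T` is mapped to
#' `ln(1 + x * scaleFactor / T)` (the standard library-size log
#' normalization of single-cell toolkits; default scale factor 10,000).
#'
#' @param x a counts [GeneEffectMatrix-class].
#' @param scaleFactor library-size scale factor.
#' @return A [GeneEffectMatrix-class] of log-normalized expression.
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
    m <- scoreMatrix(x, "genes_as_rows")
    tot <- colSums(m)
    if (any(tot == 0)) stop("cell(s) with zero total counts", call. = FALSE)
    GeneEffectMatrix(log1p(sweep(m, 2L, scaleFactor / tot, `*`)),
                     "genes_as_rows")
}
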