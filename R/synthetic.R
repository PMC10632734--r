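# Synthetic gene x cell-line fitness matrices with planted structure: a
# dominant low-rank confounder loading on a designated "mito-like" gene
# set, sparse within-complex co-essentiality, weak tissue-structured
# cell-line factors, Gaussian noise and optional missingness — the
# statistical caricature of a dependency map that the normalization
# methods assume.

#' Synthetic dependency-map configuration
#'
#' Defaults are sized for desk-scale experiments (seconds to generate,
#' stable PR curves): 800 genes x 120 cell lines, 25 disjoint complexes of
#' 3-12 genes, a rank-2 confounder over 15% of the genes with top singular
#' value 3x the strongest complex signal, unit Gaussian noise, 2%
#' missingness and 6 tissue groups with a weak shared factor.
#'
#' @param nGenes,nCells matrix dimensions.
#' @param nComplexes number of planted complexes.
#' @param complexSizeRange inclusive (min, max) complex sizes.
#' @param confounderRank rank of the planted confounder.
#' @param confounderGeneFraction fraction of genes carrying the confounder
#'   (the "mito-like" exclusion set).
#' @param confounderFromComplexes fraction of complexes planted inside the
#'   confounder gene set (mito-like complexes), so that raw co-annotation
#'   signal is confounder-dominated as in real dependency maps.
#' @param confounderStrength ratio of the confounder's top singular value
#'   to the largest complex-signal singular value (> 1 makes the
#'   confounder the dominant direction).
#' @param complexEffect scale of the shared within-complex cell-line
#'   factor.
#' @param noiseSd Gaussian noise standard deviation.
#' @param missingRate fraction of entries masked missing, in [0, 1).
#' @param nTissues number of tissue groups.
#' @param tissueEffect magnitude of the shared dependency block linking a
#'   tissue's cell lines to its lineage marker genes (2% of genes per
#'   tissue, disjoint from complexes); on the scale of `complexEffect`.
#' @param overlapComplexes if `TRUE`, the second complex additionally
#'   absorbs two genes of the first (for multi-complex attribution tests).
#' @param seed RNG seed; the whole generation is a pure function of the
#'   configuration.
#' @return named list of settings (class `"SynthConfig"`).
#' @export
SynthConfig <- function(nGenes = 800L, nCells = 120L, nComplexes = 25L,
                        complexSizeRange = c(3L, 12L), confounderRank = 2L,
                        confounderGeneFraction = 0.15,
                        confounderFromComplexes = 0.2,
                        confounderStrength = 3, complexEffect = 1,
                        noiseSd = 1, missingRate = 0.02, nTissues = 6L,
                        tissueEffect = 1, overlapComplexes = FALSE,
                        seed = 1L) {
    stopifnot(nGenes >= 8L, nCells >= 8L, missingRate >= 0, missingRate < 1,
              confounderGeneFraction >= 0, confounderGeneFraction <= 1,
              length(complexSizeRange) == 2L,
              complexSizeRange[1L] >= 2L,
              complexSizeRange[2L] >= complexSizeRange[1L])
    structure(list(nGenes = as.integer(nGenes), nCells = as.integer(nCells),
                   nComplexes = as.integer(nComplexes),
                   complexSizeRange = as.integer(complexSizeRange),
                   confounderRank = as.integer(confounderRank),
                   confounderGeneFraction = confounderGeneFraction,
                   confounderFromComplexes = confounderFromComplexes,
                   confounderStrength = confounderStrength,
                   complexEffect = complexEffect, noiseSd = noiseSd,
                   missingRate = missingRate, nTissues = as.integer(nTissues),
                   tissueEffect = tissueEffect,
                   overlapComplexes = isTRUE(overlapComplexes),
                   seed = as.integer(seed)),
              class = c("SynthConfig", "list"))
}

#' Generate a synthetic dependency map with ground truth
#'
#' The matrix is the sum of (i) a low-rank confounder whose gene loadings
#' are confined to the designated confounder gene set, scaled so its top
#' singular value is `confounderStrength` times the strongest complex
#' signal; (ii) per-complex shared cell-line factors (`complexEffect`);
#' (iii) weak per-tissue shared factors (`tissueEffect`); and (iv)
#' Gaussian noise. A uniform random mask sets `missingRate` of the entries
#' missing, independent of the values. Everything is a deterministic
#' function of the configuration (including its seed).
#'
#' @param cfg a [SynthConfig()].
#' @return list with `matrix` (a [GeneEffectMatrix-class], genes as rows,
#'   `NA` for masked entries) and `truth` (class `"SyntheticTruth"`: the
#'   complex membership map, the confounder gene set and loadings, tissue
#'   labels, and the alignment of the realized top singular vector with the
#'   planted confounder).
#' @export
generateSynthetic <- function(cfg = SynthConfig()) {
    stopifnot(inherits(cfg, "SynthConfig"))
    .withSeed(cfg$seed, .generateSynthetic(cfg))
}

.generateSynthetic <- function(cfg) {
    nG <- cfg$nGenes; nC <- cfg$nCells
    genes <- sprintf("GENE%04d", seq_len(nG))
    cells <- sprintf("ACH-%06d", seq_len(nC))
    sizes <- sample(seq(cfg$complexSizeRange[1L], cfg$complexSizeRange[2L]),
                    cfg$nComplexes, replace = TRUE)
    if (sum(sizes) > 0.5 * nG)
        stop("infeasible config: complexes would cover > 50% of genes",
             call. = FALSE)
    nConf <- round(cfg$confounderGeneFraction * nG)
    confGenes <- genes[seq_len(nConf)]
    nConfCx <- min(round(cfg$confounderFromComplexes * cfg$nComplexes),
                   cfg$nComplexes)
    # complexes: the first nConfCx live inside the confounder set
    cx <- vector("list", cfg$nComplexes)
    names(cx) <- sprintf("CPX%03d", seq_len(cfg$nComplexes))
    posConf <- 0L
    posFree <- nConf
    for (j in seq_len(cfg$nComplexes)) {
        if (j <= nConfCx && posConf + sizes[j] <= nConf) {
            cx[[j]] <- genes[posConf + seq_len(sizes[j])]
            posConf <- posConf + sizes[j]
        } else {
            if (posFree + sizes[j] > nG)
                stop("infeasible config: not enough genes for complexes",
                     call. = FALSE)
            cx[[j]] <- genes[posFree + seq_len(sizes[j])]
            posFree <- posFree + sizes[j]
        }
    }
    if (cfg$overlapComplexes && cfg$nComplexes >= 2L)
        cx[[2L]] <- unique(c(cx[[2L]], cx[[1L]][1:2]))
    # within-complex shared cell-line factors
    Cx <- matrix(0, nG, nC, dimnames = list(genes, cells))
    for (j in seq_along(cx)) {
        w <- stats::rnorm(nC)
        Cx[cx[[j]], ] <- Cx[cx[[j]], , drop = FALSE] +
            cfg$complexEffect * matrix(w, length(cx[[j]]), nC, byrow = TRUE)
    }
    sComplex <- if (any(Cx != 0)) svd(Cx, nu = 0, nv = 0)$d[1L] else 1
    # low-rank confounder confined to the confounder gene set
    d <- cfg$confounderRank
    U <- matrix(0, nG, max(d, 1L), dimnames = list(genes, NULL))
    V <- matrix(0, nC, max(d, 1L), dimnames = list(cells, NULL))
    sv <- numeric(max(d, 1L))
    Conf <- matrix(0, nG, nC)
    if (d >= 1L && nConf >= 1L) {
        for (r in seq_len(d)) {
            u <- numeric(nG)
            u[seq_len(nConf)] <- stats::rnorm(nConf)
            u <- u / sqrt(sum(u^2))
            v <- stats::rnorm(nC)
            v <- v / sqrt(sum(v^2))
            U[, r] <- u; V[, r] <- v
            sv[r] <- cfg$confounderStrength * sComplex * 0.6^(r - 1)
            Conf <- Conf + sv[r] * tcrossprod(u, v)
        }
    }
    # tissue structure: each tissue's cell lines share elevated dependency
    # on a small disjoint set of lineage marker genes (a sparse block, the
    # way tissue-of-origin signal manifests in dependency maps), not a
    # dense factor
    tissues <- sprintf("tissue%02d", seq_len(cfg$nTissues))
    tissueLabels <- stats::setNames(
        sample(rep_len(tissues, nC)), cells)
    Tis <- matrix(0, nG, nC)
    tissueMarkers <- stats::setNames(vector("list", cfg$nTissues), tissues)
    if (cfg$tissueEffect > 0) {
        nMark <- max(3L, round(0.02 * nG))
        freeGenes <- setdiff(genes, c(unlist(cx)))
        if (length(freeGenes) < nMark * cfg$nTissues)
            stop("infeasible config: not enough free genes for tissue markers",
                 call. = FALSE)
        for (ki in seq_along(tissues)) {
            markers <- freeGenes[(ki - 1L) * nMark + seq_len(nMark)]
            tissueMarkers[[ki]] <- markers
            members <- which(tissueLabels == tissues[ki])
            block <- tcrossprod(stats::rnorm(nMark, 1, 0.2),
                                stats::rnorm(length(members), 1, 0.2))
            Tis[match(markers, genes), members] <-
                Tis[match(markers, genes), members] +
                cfg$tissueEffect * block
        }
    }
    X <- Conf + Cx + Tis +
        matrix(stats::rnorm(nG * nC, sd = cfg$noiseSd), nG, nC)
    dimnames(X) <- list(genes, cells)
    alignment <- NA_real_
    if (d >= 1L && nConf >= 1L && cfg$confounderStrength > 0) {
        u1 <- svd(X, nu = 1, nv = 0)$u[, 1L]
        alignment <- abs(stats::cor(u1, U[, 1L]))
        if (cfg$confounderStrength > 1 && alignment < 0.5)
            warning("planted confounder is not the top singular direction ",
                    sprintf("(|r| = %.2f)", alignment), call. = FALSE)
    }
    if (cfg$missingRate > 0) {
        mask <- matrix(stats::runif(nG * nC) < cfg$missingRate, nG, nC)
        # never blank out a full gene profile
        mask[rowSums(mask) == nC, ] <- FALSE
        X[mask] <- NA_real_
    }
    truth <- structure(list(
        complexes = cx, confounderGenes = confGenes,
        confounderLoadings = list(u = U, v = V, d = sv),
        tissueLabels = tissueLabels, tissueMarkers = tissueMarkers,
        confounderAlignment = alignment,
        config = cfg), class = c("SyntheticTruth", "list"))
    list(matrix = GeneEffectMatrix(X, "genes_as_rows"), truth = truth)
}

#' Write synthetic ground truth in the pipeline's file dialects
#'
#' Emits the complex standard as GMT, the confounder gene set as a
#' plain-text exclusion list, tissue labels as two-column TSV and the
#' confounder gene loadings as CSV — exactly the formats the readers of
#' this package consume.
#'
#' @param truth a `"SyntheticTruth"` from [generateSynthetic()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeTruth <- function(truth, dir) {
    stopifnot(inherits(truth, "SyntheticTruth"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        standard = file.path(dir, "standard.gmt"),
        exclusion = file.path(dir, "exclusion_list.txt"),
        tissues = file.path(dir, "tissue_labels.tsv"),
        loadings = file.path(dir, "confounder_loadings.csv"))
    writeStandardGmt(CoAnnotationStandard(truth$complexes), paths["standard"])
    writeExclusionList(truth$confounderGenes, paths["exclusion"])
    writeTissueLabels(truth$tissueLabels, paths["tissues"])
    ld <- data.frame(gene_id = rownames(truth$confounderLoadings$u),
                     truth$confounderLoadings$u, check.names = FALSE)
    colnames(ld) <- c("gene_id",
                      paste0("loading", seq_len(ncol(ld) - 1L)))
    utils::write.csv(ld, paths["loadings"], row.names = FALSE, quote = FALSE)
    invisible(paths)
}
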