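# Co-annotation benchmarking: pair labeling against a complex
# standard, precision versus absolute true positives, contribution
# diversity, per-complex AUPRC, and normalized-vs-raw AUPRC deltas.

.netMatrix <- function(net) {
    if (is.matrix(net)) net else weightMatrix(net)
}

# Within-complex pairs restricted to a node set:
# data.frame(complexId, geneA, geneB) with geneA < geneB.
.complexPairs <- function(std, nodes) {
    cx <- complexes(std)
    out <- lapply(names(cx), function(id) {
        g <- intersect(cx[[id]], nodes)
        p <- .allPairs(g)
        if (nrow(p) == 0L) return(NULL)
        data.frame(complexId = id, geneA = p[, 1L], geneB = p[, 2L],
                   stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(NULL)
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Label gene pairs against a co-annotation standard
#'
#' Only pairs with both genes in the intersection of the standard's gene
#' universe and the network's node set are labeled. Positives share at
#' least one complex; negatives share none. Pairs whose two members are
#' both on the exclusion list are set aside as excluded and contribute to
#' neither true nor false positives downstream; pairs containing one or no
#' excluded gene are kept.
#'
#' @param std a [CoAnnotationStandard-class].
#' @param nodes character vector of network node (gene) ids.
#' @param exclusion optional character vector of exclusion-list gene ids.
#' @return A [PairLabelSet-class].
#' @export
buildPairLabels <- function(std, nodes, exclusion = NULL) {
    universe <- intersect(geneUniverse(std), nodes)
    if (length(universe) == 0L)
        stop("standard universe and network nodes do not intersect",
             call. = FALSE)
    universe <- sort(universe)
    cx <- complexes(std)
    inc <- vapply(cx, function(g) universe %in% g,
                  logical(length(universe)))
    inc <- matrix(inc, nrow = length(universe))
    shared <- tcrossprod(inc * 1)          # pairs sharing >= 1 complex
    p <- .allPairs(universe)
    pos <- shared[cbind(match(p[, 1L], universe),
                        match(p[, 2L], universe))] > 0
    lb <- data.frame(geneA = p[, 1L], geneB = p[, 2L], positive = pos,
                     stringsAsFactors = FALSE)
    excl <- lb[0, c("geneA", "geneB")]
    if (!is.null(exclusion) && length(exclusion)) {
        both <- lb$geneA %in% exclusion & lb$geneB %in% exclusion
        excl <- lb[both, c("geneA", "geneB")]
        lb <- lb[!both, , drop = FALSE]
    }
    rownames(lb) <- rownames(excl) <- NULL
    new("PairLabelSet", labeled = lb, excluded = excl)
}

# Deterministic ranking of labeled pairs: descending weight, then
# lexicographic pair id.
.rankPairs <- function(net, df) {
    w <- .netMatrix(net)
    miss <- !(df$geneA %in% rownames(w)) | !(df$geneB %in% rownames(w))
    if (any(miss))
        stop(sum(miss), " labeled pair(s) missing from the network",
             call. = FALSE)
    df$weight <- .pairWeights(w, df$geneA, df$geneB)
    df[order(-df$weight, df$geneA, df$geneB), , drop = FALSE]
}

#' Precision versus absolute true positives
#'
#' Orders labeled pairs from high to low similarity (ties broken by
#' lexicographic pair id) and reports, at every rank, the cumulative true
#' positive count and the running precision `TP / (TP + FP)`. The x-axis
#' quantity is the absolute TP count (recall is also reported). Excluded
#' pairs never enter the ranking.
#'
#' @param net a network object or square named weight matrix.
#' @param labels a [PairLabelSet-class] from [buildPairLabels()].
#' @return data.frame with one row per labeled pair in ranking order:
#'   `geneA`, `geneB`, `weight`, `positive`, `tp`, `precision`, `recall`;
#'   attribute `tiesPolicy`.
#' @export
prCurve <- function(net, labels) {
    stopifnot(is(labels, "PairLabelSet"))
    df <- .rankPairs(net, labels@labeled)
    nPos <- sum(df$positive)
    if (nPos == 0L) stop("no positive pairs to evaluate", call. = FALSE)
    df$tp <- cumsum(df$positive)
    rank <- seq_len(nrow(df))
    df$precision <- df$tp / rank
    df$recall <- df$tp / nPos
    rownames(df) <- NULL
    attr(df, "tiesPolicy") <- "desc_weight_then_lexicographic_pair"
    df
}

#' Contribution diversity across precision cutoffs
#'
#' For each precision cutoff, takes the largest prefix of the ranking whose
#' running precision is at or above the cutoff and reports the fraction of
#' its true-positive pairs attributed to each complex. A pair annotated to
#' `m` complexes contributes `1/m` to each, so fractions sum to 1. The top
#' 10 complexes by overall contribution keep their ids; the rest are
#' aggregated as `"other"`.
#'
#' @inheritParams prCurve
#' @param std the [CoAnnotationStandard-class] the labels came from.
#' @param precisionGrid cutoffs to slide over (high to low).
#' @param topN number of named complexes (default 10).
#' @return long data.frame (`cutoff`, `complexId`, `fraction`, `nTp`);
#'   cutoffs never attained are absent.
#' @export
diversityBreakdown <- function(net, labels, std,
                               precisionGrid = seq(0.9, 0.1, by = -0.1),
                               topN = 10L) {
    pr <- prCurve(net, labels)
    nodes <- unique(c(pr$geneA, pr$geneB))
    cp <- .complexPairs(std, nodes)
    key2cx <- split(cp$complexId, .pairKey(cp$geneA, cp$geneB))
    prKey <- .pairKey(pr$geneA, pr$geneB)
    rows <- list()
    for (cut in precisionGrid) {
        k <- which(pr$precision >= cut)
        if (!length(k)) next
        k <- max(k)
        tpIdx <- which(pr$positive[seq_len(k)])
        if (!length(tpIdx)) next
        contrib <- new.env(parent = emptyenv())
        for (i in tpIdx) {
            cxs <- key2cx[[prKey[i]]]
            share <- 1 / length(cxs)
            for (id in cxs)
                assign(id, share + mget(id, contrib, ifnotfound = 0)[[1L]],
                       envir = contrib)
        }
        ids <- ls(contrib)
        fr <- vapply(ids, get, numeric(1), envir = contrib) / length(tpIdx)
        rows[[length(rows) + 1L]] <- data.frame(
            cutoff = cut, complexId = ids, fraction = unname(fr),
            nTp = length(tpIdx), stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(cutoff = numeric(0), complexId = character(0),
                          fraction = numeric(0), nTp = integer(0)))
    out <- do.call(rbind, rows)
    tot <- tapply(out$fraction, out$complexId, sum)
    top <- names(sort(tot, decreasing = TRUE))[seq_len(min(topN, length(tot)))]
    out$complexId[!(out$complexId %in% top)] <- "other"
    agg <- stats::aggregate(fraction ~ cutoff + complexId + nTp, out, sum)
    agg[order(-agg$cutoff, agg$complexId), , drop = FALSE]
}

# Average precision (step interpolation) of a logical vector in ranked
# order: mean of running precision at the positive ranks.
.averagePrecision <- function(positive) {
    if (!any(positive)) return(0)
    prec <- cumsum(positive) / seq_along(positive)
    mean(prec[positive])
}

#' Per-complex area under the precision-recall curve
#'
#' For each complex, its within-complex pairs are the positives and the
#' within-complex pairs of all other complexes the negatives; the ranking
#' is restricted to this co-complex pair set and scored by average
#' precision. Complexes with no scored pair are omitted with a warning.
#' Excluded pairs (both genes on the exclusion list) are removed before
#' scoring.
#'
#' @inheritParams diversityBreakdown
#' @param exclusion optional exclusion gene list.
#' @return data.frame (`complexId`, `size`, `nPairs`, `auprc`) where `size`
#'   is the complex's gene count in the standard.
#' @export
perComplexAuprc <- function(net, std, exclusion = NULL) {
    w <- .netMatrix(net)
    cp <- .complexPairs(std, rownames(w))
    if (is.null(cp) || nrow(cp) == 0L)
        stop("no within-complex pair is present in the network", call. = FALSE)
    if (!is.null(exclusion) && length(exclusion)) {
        both <- cp$geneA %in% exclusion & cp$geneB %in% exclusion
        cp <- cp[!both, , drop = FALSE]
    }
    key <- .pairKey(cp$geneA, cp$geneB)
    pairs <- !duplicated(key)
    pdf <- cp[pairs, c("geneA", "geneB"), drop = FALSE]
    pdf <- .rankPairs(w, pdf)
    rankedKey <- .pairKey(pdf$geneA, pdf$geneB)
    key2cx <- split(cp$complexId, key)
    sizes <- lengths(complexes(std))
    scored <- unique(cp$complexId)
    missing <- setdiff(names(complexes(std)), scored)
    if (length(missing))
        warning(length(missing), " complex(es) with no scored pair omitted: ",
                paste(utils::head(missing, 5L), collapse = ", "),
                call. = FALSE)
    memb <- lapply(key2cx[rankedKey], unique)
    res <- lapply(scored, function(id) {
        positive <- vapply(memb, function(m) id %in% m, logical(1))
        data.frame(complexId = id, size = unname(sizes[id]),
                   nPairs = sum(positive),
                   auprc = .averagePrecision(positive),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out[order(out$complexId), , drop = FALSE]
}

.SIZE_BINS <- c("2-3", "4-5", "6-9", "10+")

.sizeBin <- function(size) {
    cut(size, breaks = c(-Inf, 3, 5, 9, Inf), labels = .SIZE_BINS)
}

#' Count complexes crossing an AUPRC threshold after normalization
#'
#' A complex counts as an "increase" when its raw AUPRC is below the
#' threshold `t` and its normalized AUPRC reaches it (`raw < t <= norm`),
#' and as a "decrease" in the opposite case (`norm < t <= raw`). Counts are
#' reported per complex-size bin (2-3, 4-5, 6-9, 10+ genes).
#'
#' @param tableNorm,tableRaw per-complex AUPRC tables from
#'   [perComplexAuprc()] on the normalized and raw networks (shared
#'   complex ids).
#' @param threshold AUPRC threshold (typical choices 0.1, 0.5, 0.7).
#' @return data.frame (`direction`, `sizeBin`, `count`) over both
#'   directions and all four bins.
#' @export
auprcDeltaCounts <- function(tableNorm, tableRaw, threshold) {
    mg <- merge(tableNorm[, c("complexId", "size", "auprc")],
                tableRaw[, c("complexId", "auprc")],
                by = "complexId", suffixes = c("Norm", "Raw"))
    bin <- .sizeBin(mg$size)
    up <- mg$auprcRaw < threshold & mg$auprcNorm >= threshold
    dn <- mg$auprcNorm < threshold & mg$auprcRaw >= threshold
    grid <- expand.grid(direction = c("increase", "decrease"),
                        sizeBin = .SIZE_BINS, stringsAsFactors = FALSE)
    grid$count <- mapply(function(d, b) {
        sel <- if (d == "increase") up else dn
        sum(sel & bin == b)
    }, grid$direction, grid$sizeBin)
    grid
}
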