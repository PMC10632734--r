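# Tissue-of-origin prediction from cell-line similarity networks.

#' k-nearest-neighbour majority-vote prediction
#'
#' Leave-one-out over all cell lines: each line's neighbours are the `K`
#' other lines with the highest similarity (ties in the neighbour ranking
#' broken by node id order), and the predicted label is the majority class
#' among the neighbours' labels. A voting tie is resolved by assigning the
#' label of the single highest-similarity neighbour.
#'
#' @param net similarity network over cell lines (object or square named
#'   matrix).
#' @param labels named character vector mapping every node id to its tissue
#'   class.
#' @param K neighbourhood size (`1 <= K <` number of cell lines).
#' @return named character vector of predicted labels.
#' @export
knnPredict <- function(net, labels, K) {
    w <- .netMatrix(net)
    ids <- rownames(w)
    n <- length(ids)
    if (!(K >= 1L && K < n)) stop("need 1 <= K < number of cell lines",
                                  call. = FALSE)
    if (!all(ids %in% names(labels)))
        stop("unlabeled cell line(s): ",
             paste(utils::head(setdiff(ids, names(labels)), 5L),
                   collapse = ", "), call. = FALSE)
    labels <- labels[ids]
    pred <- character(n)
    for (i in seq_len(n)) {
        wi <- w[i, -i]
        nb <- order(-wi)[seq_len(K)]    # order() is stable -> id-order ties
        nbLabels <- labels[-i][nb]
        tab <- table(nbLabels)
        winners <- names(tab)[tab == max(tab)]
        pred[i] <- if (length(winners) == 1L) winners else unname(nbLabels[1L])
    }
    stats::setNames(pred, ids)
}

#' Confusion matrix, per-class and weighted precision/recall/F1
#'
#' Per-class metrics come from the confusion matrix (rows = true classes,
#' columns = predicted); overall scores are support-weighted means across
#' classes. A class never predicted gets precision 0; a class with
#' precision + recall = 0 gets F1 = 0.
#'
#' @param predictions named character vector of predicted labels.
#' @param truth named character vector of true labels (same names).
#' @return list with `confusion` (classes x classes integer matrix),
#'   `perClass` data.frame (`class`, `support`, `precision`, `recall`,
#'   `f1`) and `overall` named numeric (`precision`, `recall`, `f1`).
#' @export
weightedPrf <- function(predictions, truth) {
    ids <- names(truth)
    stopifnot(!is.null(ids), all(ids %in% names(predictions)))
    predictions <- predictions[ids]
    classes <- sort(unique(c(truth, predictions)))
    cm <- table(factor(truth, classes), factor(predictions, classes))
    cm <- matrix(as.integer(cm), length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
    tp <- diag(cm)
    support <- rowSums(cm)
    predTot <- colSums(cm)
    precision <- ifelse(predTot > 0, tp / predTot, 0)
    recall <- ifelse(support > 0, tp / support, 0)
    f1 <- ifelse(precision + recall > 0,
                 2 * precision * recall / (precision + recall), 0)
    wts <- support / sum(support)
    list(confusion = cm,
         perClass = data.frame(class = classes, support = as.integer(support),
                               precision = unname(precision),
                               recall = unname(recall), f1 = unname(f1),
                               stringsAsFactors = FALSE),
         overall = c(precision = sum(wts * precision),
                     recall = sum(wts * recall),
                     f1 = sum(wts * f1)))
}

#' Random-classifier baseline
#'
#' Each iteration predicts every cell line's label by drawing uniformly at
#' random from the observed label multiset; the reported baseline is the
#' mean weighted precision/recall/F1 over the iterations (100 by default),
#' under a fixed seed.
#'
#' @param truth named character vector of true labels.
#' @param iterations number of random draws (default 100).
#' @param seed RNG seed.
#' @return named numeric (`precision`, `recall`, `f1`) of mean baseline
#'   scores.
#' @export
randomBaseline <- function(truth, iterations = 100L, seed = 1L) {
    stopifnot(iterations >= 1L)
    scores <- .withSeed(seed, vapply(seq_len(iterations), function(i) {
        pred <- stats::setNames(
            sample(unname(truth), length(truth), replace = TRUE),
            names(truth))
        weightedPrf(pred, truth)$overall
    }, numeric(3)))
    rowMeans(scores)
}
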