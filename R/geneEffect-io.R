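#' Read a DepMap-style gene effect CSV
#'
#' Parses the CSV dialect distributed with dependency-map releases
#' (`Achilles_gene_effect.csv` / `CRISPRGeneEffect.csv`): a header row, the
#' first column holding sample (cell line) ids, and remaining column headers
#' of the form `"SYMBOL (EntrezID)"`. Empty cells and `NA` mark missing
#' scores. The gene id kept is the symbol portion before `" ("`; duplicated
#' symbols are disambiguated by suffixing (`.1`, `.2`, ...) with a warning.
#'
#' The returned object is always in the canonical `genes_as_rows`
#' orientation; the transpose from the on-disk layout is explicit here.
#'
#' @param path path to the CSV file.
#' @param orientationHint layout of the file on disk: `"samples_as_rows"`
#'   (the DepMap convention, default) or `"genes_as_rows"`.
#' @return A [GeneEffectMatrix-class] with genes as rows.
#' @seealso [writeGeneEffectCsv()]
#' @export
readGeneEffectCsv <- function(path,
        orientationHint = c("samples_as_rows", "genes_as_rows")) {
    orientationHint <- match.arg(orientationHint)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    dt <- tryCatch(
        data.table::fread(path, header = TRUE, sep = ",", fill = FALSE,
                          na.strings = c("", "NA"), data.table = FALSE,
                          colClasses = list(character = 1)),
        error = function(e) stop("malformed gene effect CSV '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (ncol(dt) < 2L)
        stop("gene effect CSV has no data columns: ", path, call. = FALSE)
    rowIds <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric data column in ", path, " (first offending column: ",
             colnames(m)[which(!apply(m, 2, is.numeric))[1L]], ")",
             call. = FALSE)
    storage.mode(m) <- "double"
    colIds <- sub(" \\(.*$", "", colnames(dt)[-1L])
    dup <- duplicated(colIds)
    if (any(dup)) {
        warning(sum(dup), " duplicated gene symbol(s) disambiguated by suffix: ",
                paste(unique(colIds[dup]), collapse = ", "), call. = FALSE)
        colIds <- make.unique(colIds)
    }
    if (anyDuplicated(rowIds))
        stop("duplicated sample ids in first column of ", path, call. = FALSE)
    if (nrow(m) == 0L) stop("zero data rows in ", path, call. = FALSE)
    dimnames(m) <- list(rowIds, colIds)
    if (orientationHint == "samples_as_rows")
        GeneEffectMatrix(t(m), "genes_as_rows")
    else
        GeneEffectMatrix(m, "genes_as_rows")
}

#' Write a GeneEffectMatrix as a DepMap-style CSV
#'
#' Emits the `samples_as_rows` on-disk dialect: first column the sample ids,
#' remaining headers `"SYMBOL (i)"` with a sequential surrogate id.
#'
#' @param x a [GeneEffectMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneEffectCsv <- function(x, path) {
    m <- scoreMatrix(x, "samples_as_rows")
    hdr <- sprintf("%s (%d)", colnames(m), seq_len(ncol(m)))
    df <- data.frame(DepMap_ID = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("DepMap_ID", hdr)
    data.table::fwrite(df, path, na = "", quote = FALSE)
    invisible(path)
}

#' Read / write a plain-text exclusion gene list
#'
#' One gene id per line (a mitochondria-like exclusion set); blank lines and
#' lines starting with `#` are ignored. The list need not be a subset of any
#' data's gene universe.
#'
#' @param path text file path.
#' @return `readExclusionList`: character vector of unique gene ids.
#' @export
readExclusionList <- function(path) {
    x <- readLines(path, warn = FALSE)
    x <- trimws(x)
    unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname readExclusionList
#' @param genes character vector of gene ids.
#' @export
writeExclusionList <- function(genes, path) {
    writeLines(unique(as.character(genes)), path)
    invisible(path)
}

#' Read a co-annotation standard (GMT or two-column TSV)
#'
#' GMT: one complex per line, `id <tab> description <tab> gene...`.
#' TSV: two columns `complex_id <tab> gene`, no header required (a header
#' line whose second field is literally `"gene"` is skipped).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return A [CoAnnotationStandard-class].
#' @export
readCoAnnotationStandard <- function(path, format = c("auto", "gmt", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
    if (format == "gmt") {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[nzchar(trimws(lines))]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        bad <- which(lengths(parts) < 4L)  # id + desc + >= 2 genes
        if (length(bad))
            stop("GMT line ", bad[1L], " has fewer than two member genes",
                 call. = FALSE)
        cx <- lapply(parts, function(p) p[-(1:2)])
        names(cx) <- vapply(parts, `[[`, character(1), 1L)
    } else {
        df <- utils::read.table(path, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
        if (ncol(df) < 2L) stop("TSV standard needs two columns", call. = FALSE)
        if (nrow(df) && identical(tolower(df[2L][1, ]), "gene"))
            df <- df[-1L, , drop = FALSE]
        cx <- split(df[[2L]], df[[1L]])
    }
    CoAnnotationStandard(cx)
}

#' @rdname readCoAnnotationStandard
#' @param std a [CoAnnotationStandard-class].
#' @export
writeStandardGmt <- function(std, path) {
    cx <- complexes(std)
    lines <- vapply(names(cx), function(id)
        paste(c(id, id, cx[[id]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write tissue (lineage) labels
#'
#' Two-column TSV `cell_line_id <tab> lineage`, with or without a header.
#'
#' @param path file path.
#' @return named character vector of labels (names = cell line ids).
#' @export
readTissueLabels <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
    if (nrow(df) && tolower(df[1L, 1L]) %in% c("cell_line_id", "cell_line"))
        df <- df[-1L, , drop = FALSE]
    stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname readTissueLabels
#' @param labels named character vector.
#' @export
writeTissueLabels <- function(labels, path) {
    utils::write.table(
        data.frame(cell_line_id = names(labels), lineage = unname(labels)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Serialize a network as a sorted edge-list TSV
#'
#' Columns `node_a`, `node_b`, `weight` with `node_a < node_b`, sorted by
#' descending weight (ties by pair id).
#'
#' @param net a network object or square named weight matrix.
#' @param path output TSV.
#' @return `path` invisibly; `readEdgeList` returns the edge data.frame.
#' @export
writeEdgeList <- function(net, path) {
    w <- if (is.matrix(net)) net else weightMatrix(net)
    p <- .allPairs(rownames(w))
    wt <- .pairWeights(w, p[, 1L], p[, 2L])
    o <- order(-wt, p[, 1L], p[, 2L])
    utils::write.table(
        data.frame(node_a = p[o, 1L], node_b = p[o, 2L], weight = wt[o]),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "numeric"))
}

#' Export an edge network as GraphML
#'
#' Writes a Cytoscape-importable GraphML file with edge attribute `weight`
#' and boolean node attribute `in_exclusion_list`.
#'
#' @param edges data.frame with columns `nodeA`, `nodeB`, `weight` (as
#'   returned by [topEdges()]).
#' @param path output file.
#' @param exclusion optional character vector of exclusion-list gene ids.
#' @return `path`, invisibly.
#' @export
writeGraphml <- function(edges, path, exclusion = character(0)) {
    g <- igraph::graph_from_data_frame(
        edges[, c("nodeA", "nodeB", "weight")], directed = FALSE)
    igraph::V(g)$in_exclusion_list <- igraph::V(g)$name %in% exclusion
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
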