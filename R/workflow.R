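# Workflow runner tying the modules into the three analysis paths (gene
# networks, cell-line lineage, expression) plus simulation and
# benchmarking. The thin command-line wrapper in inst/scripts/onion.R
# forwards to runWorkflow().

.writeManifest <- function(outDir, config, extra = list()) {
    manifest <- c(list(
        package = "onionnet",
        version = as.character(utils::packageVersion("onionnet")),
        timestamp = format(Sys.time(), tz = "UTC"),
        config = config), extra)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.writeFused <- function(fused, outDir, stem) {
    writeEdgeList(fused, file.path(outDir, paste0(stem, "_edges.tsv")))
    utils::write.csv(weightMatrix(fused),
                     file.path(outDir, paste0(stem, "_weights.csv")))
}

#' Run a named workflow end to end
#'
#' Workflows: `"simulate"` (generate a synthetic dependency map and its
#' ground-truth files), `"gene_network"` (impute + onion pipeline on a gene
#' effect CSV), `"cell_line"` (cell-line onion network + kNN
#' tissue-of-origin report), `"expression"` (MTX counts -> filters ->
#' log-normalization -> RPCA layers -> max-weight fusion) and
#' `"benchmark"` (PR curve, diversity and per-complex AUPRC of a stored
#' network against a standard). Every run writes its artifacts plus a
#' manifest (configuration, package version, seed) into `outDir`, so the
#' output directory is self-describing.
#'
#' @param config named list; required fields per workflow are `workflow`
#'   and `outDir`, plus: `input` (CSV path or MTX directory), `method` and
#'   `grid` (gene_network/cell_line), `standard`/`exclusion`
#'   (benchmark), `labels` (cell_line), `synth` (a [SynthConfig()] for
#'   simulate), `sigma`, `kNeighbors`, `iterations`, `K`, `seed`.
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
runWorkflow <- function(config) {
    wf <- match.arg(config$workflow,
                    c("simulate", "gene_network", "cell_line", "expression",
                      "benchmark"))
    outDir <- config$outDir
    if (is.null(outDir)) stop("config$outDir is required", call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    extra <- switch(wf,
        simulate = {
            synth <- config$synth
            if (is.null(synth)) synth <- SynthConfig()
            sim <- generateSynthetic(synth)
            writeGeneEffectCsv(sim$matrix,
                               file.path(outDir, "gene_effect.csv"))
            writeTruth(sim$truth, outDir)
            list(nGenes = synth$nGenes, nCells = synth$nCells)
        },
        gene_network = {
            x <- imputeGeneMean(readGeneEffectCsv(config$input))
            fused <- onionPipeline(x, method = config$method,
                                   grid = config$grid,
                                   config = .fusionFromConfig(config))
            .writeFused(fused, outDir, "fused")
            list(nNodes = length(nodeIds(fused)))
        },
        cell_line = {
            x <- imputeGeneMean(readGeneEffectCsv(config$input))
            fused <- onionPipeline(x, method = config$method %||% "rpca",
                                   grid = config$grid, kind = "cell_line",
                                   config = .fusionFromConfig(config))
            .writeFused(fused, outDir, "fused_cell_line")
            labels <- readTissueLabels(config$labels)
            K <- config$K %||% 5L
            pred <- knnPredict(fused, labels, K = K)
            rep <- weightedPrf(pred, labels[nodeIds(fused)])
            base <- randomBaseline(labels[nodeIds(fused)],
                                   seed = config$seed %||% 1L)
            jsonlite::write_json(
                list(K = K, overall = as.list(rep$overall),
                     baseline = as.list(base), perClass = rep$perClass),
                file.path(outDir, "knn_report.json"),
                auto_unbox = TRUE, digits = NA, pretty = TRUE)
            utils::write.csv(rep$confusion,
                             file.path(outDir, "confusion_matrix.csv"))
            list(weightedF1 = unname(rep$overall["f1"]))
        },
        expression = {
            counts <- readCountsMtx(config$input)
            expr <- logNormalize(filterExpression(counts))
            grid <- config$grid %||% defaultGrid("rpca")
            nets <- lapply(grid, function(f)
                pccNetwork(rpcaNormalize(expr, f = f)$normalized))
            fused <- maxFuse(nets, provenance = sprintf("rpca:%g", grid))
            .writeFused(fused, outDir, "fused_expression")
            list(nNodes = length(nodeIds(fused)))
        },
        benchmark = {
            w <- as.matrix(utils::read.csv(config$input, row.names = 1,
                                           check.names = FALSE))
            colnames(w) <- rownames(w)
            std <- readCoAnnotationStandard(config$standard)
            excl <- if (!is.null(config$exclusion))
                readExclusionList(config$exclusion) else NULL
            labels <- buildPairLabels(std, rownames(w), exclusion = excl)
            pr <- prCurve(w, labels)
            utils::write.table(pr, file.path(outDir, "pr_curve.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            dv <- diversityBreakdown(w, labels, std)
            utils::write.table(dv, file.path(outDir, "diversity.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            ap <- perComplexAuprc(w, std, exclusion = excl)
            utils::write.table(ap, file.path(outDir, "per_complex_auprc.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            jsonlite::write_json(
                list(nPositive = sum(labels@labeled$positive),
                     nNegative = sum(!labels@labeled$positive),
                     nExcluded = nrow(labels@excluded),
                     finalPrecision = pr$precision[nrow(pr)],
                     medianAuprc = stats::median(ap$auprc)),
                file.path(outDir, "benchmark_summary.json"),
                auto_unbox = TRUE, digits = NA, pretty = TRUE)
            list(nComplexesScored = nrow(ap))
        })
    .writeManifest(outDir, config, extra)
    invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fusionFromConfig <- function(config) {
    FusionConfig(method = config$method %||% "rpca",
                 sigma = config$sigma,
                 kNeighbors = config$kNeighbors %||% 5L,
                 iterations = config$iterations %||% 10L,
                 includeUnnormalizedLayer = config$includeUnnormalizedLayer)
}
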