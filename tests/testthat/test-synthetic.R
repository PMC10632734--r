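test_that("a noiseless single complex yields perfect within-complex PCC", {
    cfg <- SynthConfig(nGenes = 40, nCells = 12, nComplexes = 1,
                       complexSizeRange = c(4, 4), confounderRank = 0,
                       confounderGeneFraction = 0, confounderFromComplexes = 0,
                       noiseSd = 0, tissueEffect = 0, missingRate = 0,
                       seed = 5)
    sim <- generateSynthetic(cfg)
    members <- sim$truth$complexes[[1]]
    m <- scoreMatrix(sim$matrix)[members, ]
    cc <- cor(t(m))
    expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)
})

test_that("the planted confounder dominates the top singular direction", {
    sim <- generateSynthetic(SynthConfig(nGenes = 300, nCells = 40,
                                         confounderRank = 1,
                                         confounderStrength = 3,
                                         nComplexes = 8,
                                         complexSizeRange = c(3, 6),
                                         missingRate = 0, seed = 6))
    X <- scoreMatrix(sim$matrix)
    u1 <- svd(X, nu = 1, nv = 0)$u[, 1]
    expect_gt(abs(cor(u1, sim$truth$confounderLoadings$u[, 1])), 0.95)
    expect_gt(sim$truth$confounderAlignment, 0.95)
})

test_that("generation is a pure function of the configuration", {
    cfg <- SynthConfig(nGenes = 60, nCells = 16, nComplexes = 4,
                       complexSizeRange = c(3, 4), seed = 8)
    a <- generateSynthetic(cfg)
    b <- generateSynthetic(cfg)
    expect_identical(scoreMatrix(a$matrix), scoreMatrix(b$matrix))
    expect_identical(a$truth$tissueLabels, b$truth$tissueLabels)
    # a different seed gives different data
    c2 <- generateSynthetic(SynthConfig(nGenes = 60, nCells = 16,
                                        nComplexes = 4,
                                        complexSizeRange = c(3, 4), seed = 9))
    expect_false(identical(scoreMatrix(a$matrix), scoreMatrix(c2$matrix)))
})

test_that("ground-truth files round-trip through the package readers", {
    cfg <- SynthConfig(nGenes = 80, nCells = 16, nComplexes = 5,
                       complexSizeRange = c(3, 4), seed = 10)
    sim <- generateSynthetic(cfg)
    dir <- withr::local_tempdir()
    paths <- writeTruth(sim$truth, dir)
    std <- readCoAnnotationStandard(paths["standard"])
    expect_identical(complexes(std), sim$truth$complexes)
    expect_identical(length(readLines(paths["standard"])), 5L)
    excl <- readExclusionList(paths["exclusion"])
    expect_identical(excl, sim$truth$confounderGenes)
    expect_identical(length(excl), as.integer(round(0.15 * 80)))
    labs <- readTissueLabels(paths["tissues"])
    expect_identical(labs[names(sim$truth$tissueLabels)],
                     sim$truth$tissueLabels)
    # the emitted DepMap-style CSV reloads identically (NAs preserved)
    f <- file.path(dir, "ge.csv")
    writeGeneEffectCsv(sim$matrix, f)
    back <- readGeneEffectCsv(f)
    expect_equal(scoreMatrix(back), scoreMatrix(sim$matrix),
                 tolerance = 1e-12)
})

test_that("within-complex correlation exceeds between-complex correlation", {
    pvals <- vapply(1:3, function(s) {
        sim <- generateSynthetic(SynthConfig(nGenes = 120, nCells = 30,
                                             nComplexes = 6,
                                             complexSizeRange = c(4, 6),
                                             confounderRank = 0,
                                             confounderGeneFraction = 0,
                                             confounderFromComplexes = 0,
                                             missingRate = 0, seed = 100 + s))
        w <- weightMatrix(pccNetwork(sim$matrix))
        cx <- sim$truth$complexes
        within <- unlist(lapply(cx, function(g) {
            sub <- w[g, g]; sub[upper.tri(sub)]
        }))
        btwn <- c()
        ids <- names(cx)
        for (i in seq_along(ids))
            for (j in seq_along(ids))
                if (i < j) btwn <- c(btwn, as.numeric(w[cx[[i]], cx[[j]]]))
        t.test(within, btwn, alternative = "greater")$p.value
    }, numeric(1))
    expect_true(all(pvals < 0.01))
})

test_that("raw top edges are confounder-enriched; RPCA reduces it", {
    ors <- vapply(1:2, function(s) {
        sim <- generateSynthetic(SynthConfig(nGenes = 200, nCells = 40,
                                             nComplexes = 8,
                                             complexSizeRange = c(3, 6),
                                             missingRate = 0, seed = 200 + s))
        conf <- sim$truth$confounderGenes
        fisherOr <- function(net) {
            e <- topEdges(net, 200)
            inConf <- e$nodeA %in% conf & e$nodeB %in% conf
            ids <- nodeIds(net)
            p <- onionnet:::.allPairs(ids)
            allConf <- p[, 1] %in% conf & p[, 2] %in% conf
            k <- sum(inConf)
            tab <- matrix(c(k, 200 - k, sum(allConf) - k,
                            nrow(p) - 200 - sum(allConf) + k), 2)
            fisher.test(tab)$estimate
        }
        raw <- fisherOr(pccNetwork(sim$matrix))
        norm <- fisherOr(pccNetwork(
            rpcaNormalize(imputeGeneMean(sim$matrix))$normalized))
        c(raw = raw, norm = norm)
    }, numeric(2))
    expect_true(all(ors[1, ] > ors[2, ]))
})

test_that("the missingness mask is independent of the underlying values", {
    cors <- vapply(1:5, function(s) {
        cfg <- SynthConfig(nGenes = 100, nCells = 30, nComplexes = 5,
                           complexSizeRange = c(3, 4), missingRate = 0.1,
                           seed = 300 + s)
        withNA <- scoreMatrix(generateSynthetic(cfg)$matrix)
        cfg0 <- cfg; cfg0$missingRate <- 0
        full <- scoreMatrix(generateSynthetic(cfg0)$matrix)
        cor(as.numeric(is.na(withNA)), abs(as.numeric(full)))
    }, numeric(1))
    expect_lt(abs(mean(cors)), 0.02)
    expect_true(all(abs(cors) < 0.08))
})

test_that("infeasible configurations are refused", {
    expect_error(generateSynthetic(
        SynthConfig(nGenes = 40, nCells = 12, nComplexes = 10,
                    complexSizeRange = c(4, 4), seed = 1)),
        "infeasible")
})

test_that("overlapping complexes can be requested for attribution tests", {
    sim <- generateSynthetic(SynthConfig(nGenes = 80, nCells = 16,
                                         nComplexes = 4,
                                         complexSizeRange = c(3, 4),
                                         overlapComplexes = TRUE, seed = 2))
    shared <- intersect(sim$truth$complexes[[1]], sim$truth$complexes[[2]])
    expect_identical(length(shared), 2L)
})
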