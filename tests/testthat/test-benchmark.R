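toyStandard <- function() {
    CoAnnotationStandard(list(A = c("g1", "g2", "g3"), B = c("g4", "g5")))
}

test_that("pair labeling follows co-complex membership", {
    std <- CoAnnotationStandard(list(A = c("g1", "g2", "g3")))
    lb <- buildPairLabels(std, c("g1", "g2", "g3", "g4"))
    pos <- lb@labeled[lb@labeled$positive, ]
    expect_identical(paste(pos$geneA, pos$geneB),
                     c("g1 g2", "g1 g3", "g2 g3"))
    # g4 is outside the standard's universe: unlabeled entirely
    expect_false("g4" %in% c(lb@labeled$geneA, lb@labeled$geneB))
    expect_error(buildPairLabels(std, c("x1", "x2")), "intersect")
})

test_that("exclusion removes only pairs with both genes excluded", {
    std <- CoAnnotationStandard(list(A = c("g1", "g2", "g3")))
    lb <- buildPairLabels(std, c("g1", "g2", "g3"),
                          exclusion = c("g1", "g2"))
    expect_identical(nrow(lb@excluded), 1L)
    expect_identical(paste(lb@excluded$geneA, lb@excluded$geneB), "g1 g2")
    expect_true(any(lb@labeled$geneA == "g1" & lb@labeled$geneB == "g3"))
})

test_that("overlapping complexes yield each positive pair once", {
    std <- CoAnnotationStandard(list(A = c("g1", "g2", "g3"),
                                     B = c("g2", "g3", "g4")))
    lb <- buildPairLabels(std, c("g1", "g2", "g3", "g4"))
    key <- paste(lb@labeled$geneA, lb@labeled$geneB)
    expect_identical(anyDuplicated(key), 0L)
    expect_identical(sum(lb@labeled$positive), 5L)  # 3 + 3 - (g2,g3) shared
})

test_that("precision sequences match hand enumeration", {
    std <- toyStandard()
    # ranking: (g1,g2)+ 0.9, (g1,g4)- 0.8, (g1,g3)+ 0.7, rest low
    net <- toyNetwork(paste0("g", 1:5), list(
        list("g1", "g2", 0.9), list("g1", "g4", 0.8), list("g1", "g3", 0.7),
        list("g2", "g3", 0.1), list("g4", "g5", 0.05)))
    lb <- buildPairLabels(std, paste0("g", 1:5))
    pr <- prCurve(net, lb)
    expect_identical(pr$precision[1:3], c(1, 1 / 2, 2 / 3))
    expect_identical(pr$tp[1:3], c(1L, 1L, 2L))
    # final precision equals the positive fraction among labeled pairs
    expect_equal(pr$precision[nrow(pr)],
                 mean(lb@labeled$positive), tolerance = 1e-12)
    # a perfect ranking holds precision 1 at every TP count
    perfect <- toyNetwork(paste0("g", 1:5), list(
        list("g1", "g2", 0.9), list("g1", "g3", 0.8), list("g2", "g3", 0.7),
        list("g4", "g5", 0.6)))
    prP <- prCurve(perfect, lb)
    expect_true(all(prP$precision[prP$positive] == 1))
    # reversing all weights gives the worst case: positives ranked last
    wm <- perfect
    wRev <- 1 - wm; diag(wRev) <- 1
    dimnames(wRev) <- dimnames(wm)
    prR <- prCurve(wRev, lb)
    expect_identical(prR$positive, rev(prP$positive))
})

test_that("benchmark outputs are invariant to monotone weight transforms", {
    set.seed(91)
    sim <- generateSynthetic(SynthConfig(nGenes = 60, nCells = 20,
                                         nComplexes = 4,
                                         complexSizeRange = c(3, 4),
                                         missingRate = 0, seed = 33))
    net <- pccNetwork(sim$matrix)
    std <- CoAnnotationStandard(sim$truth$complexes)
    lb <- buildPairLabels(std, nodeIds(net))
    w <- weightMatrix(net)
    wt <- tanh(3 * w) + 2          # strictly increasing
    dimnames(wt) <- dimnames(w)
    pr1 <- prCurve(w, lb); pr2 <- prCurve(wt, lb)
    expect_identical(pr1$precision, pr2$precision)
    ap1 <- perComplexAuprc(w, std); ap2 <- perComplexAuprc(wt, std)
    expect_identical(ap1$auprc, ap2$auprc)
})

test_that("excluded pairs change no benchmark output", {
    set.seed(92)
    sim <- generateSynthetic(SynthConfig(nGenes = 80, nCells = 20,
                                         nComplexes = 6,
                                         complexSizeRange = c(3, 5),
                                         missingRate = 0, seed = 44))
    net <- pccNetwork(sim$matrix)
    std <- CoAnnotationStandard(sim$truth$complexes)
    excl <- sim$truth$complexes[[1]]   # exclude a whole complex
    w <- weightMatrix(net)
    lbE <- buildPairLabels(std, nodeIds(net), exclusion = excl)
    # inject top scores for the excluded pairs: outputs must not move
    wHot <- w
    ep <- lbE@excluded
    for (r in seq_len(nrow(ep)))
        wHot[ep$geneA[r], ep$geneB[r]] <- wHot[ep$geneB[r], ep$geneA[r]] <- 1
    expect_identical(prCurve(w, lbE)$precision, prCurve(wHot, lbE)$precision)
    expect_identical(
        suppressWarnings(perComplexAuprc(w, std, exclusion = excl))$auprc,
        suppressWarnings(perComplexAuprc(wHot, std, exclusion = excl))$auprc)
    dv1 <- diversityBreakdown(w, lbE, std)
    dv2 <- diversityBreakdown(wHot, lbE, std)
    expect_identical(dv1, dv2)
})

test_that("diversity fractions attribute TPs per complex and sum to 1", {
    std <- CoAnnotationStandard(list(A = c("g1", "g2", "g3")))
    net <- toyNetwork(paste0("g", 1:4), list(
        list("g1", "g2", 0.9), list("g1", "g3", 0.8), list("g2", "g3", 0.7)))
    lb <- buildPairLabels(std, paste0("g", 1:4))
    dv <- diversityBreakdown(net, lb, std, precisionGrid = c(0.9, 0.5))
    expect_true(all(dv$fraction == 1))
    expect_true(all(dv$complexId == "A"))
    # 3:1 contribution at an attained cutoff
    std2 <- CoAnnotationStandard(list(A = c("g1", "g2", "g3"),
                                      B = c("g4", "g5")))
    net2 <- toyNetwork(paste0("g", 1:5), list(
        list("g1", "g2", 0.9), list("g1", "g3", 0.85), list("g2", "g3", 0.8),
        list("g4", "g5", 0.75)))
    lb2 <- buildPairLabels(std2, paste0("g", 1:5))
    dv2 <- diversityBreakdown(net2, lb2, std2, precisionGrid = 1)
    expect_equal(dv2$fraction[dv2$complexId == "A"], 0.75)
    expect_equal(dv2$fraction[dv2$complexId == "B"], 0.25)
    # a pair in two complexes is attributed fractionally; sums stay 1
    std3 <- CoAnnotationStandard(list(A = c("g1", "g2"), B = c("g1", "g2")))
    net3 <- toyNetwork(c("g1", "g2"), list(list("g1", "g2", 0.9)))
    dv3 <- diversityBreakdown(net3, buildPairLabels(std3, c("g1", "g2")),
                              std3, precisionGrid = 0.5)
    expect_equal(sum(dv3$fraction), 1, tolerance = 1e-12)
    expect_equal(dv3$fraction, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("per-complex AUPRC matches exhaustive average precision", {
    set.seed(93)
    sim <- generateSynthetic(SynthConfig(nGenes = 60, nCells = 20,
                                         nComplexes = 3,
                                         complexSizeRange = c(3, 4),
                                         missingRate = 0, seed = 55))
    net <- pccNetwork(sim$matrix)
    std <- CoAnnotationStandard(sim$truth$complexes)
    tab <- perComplexAuprc(net, std)
    w <- weightMatrix(net)
    # oracle: enumerate all co-complex pairs, rank, compute AP per complex
    cxp <- list()
    for (id in names(sim$truth$complexes)) {
        g <- sort(sim$truth$complexes[[id]])
        for (i in seq_along(g)) for (j in seq_along(g)) if (i < j)
            cxp[[length(cxp) + 1]] <- c(id, g[i], g[j])
    }
    df <- unique(do.call(rbind, lapply(cxp, function(x)
        data.frame(a = x[2], b = x[3]))))
    df$w <- w[cbind(df$a, df$b)]
    df <- df[order(-df$w, df$a, df$b), ]
    for (id in tab$complexId) {
        members <- sim$truth$complexes[[id]]
        positive <- df$a %in% members & df$b %in% members
        expect_equal(tab$auprc[tab$complexId == id],
                     oracleAveragePrecision(positive), tolerance = 1e-12)
    }
    # dominance: a complex occupying the top of the ranking scores highest
    topCx <- names(sim$truth$complexes)[
        vapply(sim$truth$complexes, function(g) df$a[1] %in% g &&
                   df$b[1] %in% g, logical(1))]
    expect_true(length(topCx) >= 1)
})

test_that("random rankings score near the positive prevalence", {
    set.seed(94)
    n <- 300
    positive <- c(rep(TRUE, 30), rep(FALSE, 270))
    aps <- replicate(100, oracleAveragePrecision(sample(positive)))
    prev <- mean(positive)
    # package AP on the same shuffles agrees and centres on prevalence
    expect_lt(abs(mean(aps) - prev), 3 * sd(aps))
    shuffled <- sample(positive)
    expect_equal(onionnet:::.averagePrecision(shuffled),
                 oracleAveragePrecision(shuffled), tolerance = 1e-12)
})

test_that("AUPRC delta counts bin complexes by size and direction", {
    tRaw <- data.frame(complexId = c("A", "B", "C", "D"),
                       size = c(2, 5, 7, 12), nPairs = 1,
                       auprc = c(0.05, 0.60, 0.40, 0.80))
    tNorm <- data.frame(complexId = c("A", "B", "C", "D"),
                        size = c(2, 5, 7, 12), nPairs = 1,
                        auprc = c(0.60, 0.20, 0.55, 0.80))
    same <- auprcDeltaCounts(tRaw, tRaw, 0.5)
    expect_identical(sum(same$count), 0L)
    d <- auprcDeltaCounts(tNorm, tRaw, 0.5)
    expect_identical(d$count[d$direction == "increase" & d$sizeBin == "2-3"], 1L)
    expect_identical(d$count[d$direction == "increase" & d$sizeBin == "6-9"], 1L)
    expect_identical(d$count[d$direction == "decrease" & d$sizeBin == "4-5"], 1L)
    expect_identical(sum(d$count), 3L)
    # randomized tables agree with direct enumeration
    set.seed(95)
    ids <- sprintf("C%02d", 1:40)
    szs <- sample(2:15, 40, replace = TRUE)
    a <- data.frame(complexId = ids, size = szs, nPairs = 1,
                    auprc = runif(40))
    b <- data.frame(complexId = ids, size = szs, nPairs = 1,
                    auprc = runif(40))
    for (t in c(0.1, 0.5, 0.7)) {
        d2 <- auprcDeltaCounts(a, b, t)
        expect_identical(sum(d2$count[d2$direction == "increase"]),
                         sum(b$auprc < t & a$auprc >= t))
        expect_identical(sum(d2$count[d2$direction == "decrease"]),
                         sum(a$auprc < t & b$auprc >= t))
    }
})

test_that("standards round-trip through GMT and TSV", {
    std <- toyStandard()
    f <- withr::local_tempfile(fileext = ".gmt")
    writeStandardGmt(std, f)
    expect_identical(length(readLines(f)), 2L)
    back <- readCoAnnotationStandard(f)
    expect_identical(complexes(back), complexes(std))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("A\tg1", "A\tg2", "B\tg3", "B\tg4"), tsv)
    std2 <- readCoAnnotationStandard(tsv)
    expect_identical(geneUniverse(std2), c("g1", "g2", "g3", "g4"))
})
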