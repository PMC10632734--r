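test_that("gene effect CSV parsing handles the DepMap dialect", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("DepMap_ID,A1BG (1),NAT2 (10),CDH2 (1000)",
                 "ACH-000001,0.1,,-0.3",
                 "ACH-000002,0.2,0.5,-0.6"), f)
    gem <- readGeneEffectCsv(f)
    expect_s4_class(gem, "GeneEffectMatrix")
    expect_identical(orientation(gem), "genes_as_rows")
    expect_identical(geneIds(gem), c("A1BG", "NAT2", "CDH2"))
    expect_identical(sampleIds(gem), c("ACH-000001", "ACH-000002"))
    expect_identical(sum(is.na(scoreMatrix(gem))), 1L)
    expect_identical(scoreMatrix(gem)["NAT2", "ACH-000002"], 0.5)
})

test_that("duplicated gene columns are disambiguated with a warning", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,TP53 (7157),TP53 (999999)",
                 "s1,0.1,0.2", "s2,0.3,0.4"), f)
    expect_warning(gem <- readGeneEffectCsv(f), "duplicated")
    expect_identical(geneIds(gem), c("TP53", "TP53.1"))
})

test_that("malformed gene effect CSVs raise parse errors", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,g1 (1),g2 (2)", "s1,0.1,0.2,9.9", "s2,0.3"), f)
    expect_error(readGeneEffectCsv(f), "malformed|column")
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeLines("id", f2)
    expect_error(readGeneEffectCsv(f2), "no data columns")
})

test_that("CSV round-trip preserves values and labels", {
    gem <- randGem(7, 5, seed = 42)
    f <- withr::local_tempfile(fileext = ".csv")
    writeGeneEffectCsv(gem, f)
    back <- readGeneEffectCsv(f)
    expect_identical(geneIds(back), geneIds(gem))
    expect_identical(sampleIds(back), sampleIds(gem))
    expect_lt(max(abs(scoreMatrix(back) - scoreMatrix(gem))), 1e-12)
})

test_that("gene-mean imputation fills exactly the missing entries", {
    m <- rbind(c(1, NA, 3), c(2, 2, 2))
    gem <- makeGem(m)
    out <- imputeGeneMean(gem)
    expect_identical(scoreMatrix(out)[1, ], c(s01 = 1, s02 = 2, s03 = 3))
    # observed entries bit-identical, idempotent, no-missing identity
    full <- randGem(20, 10, seed = 7)
    expect_identical(scoreMatrix(imputeGeneMean(full)), scoreMatrix(full))
    set.seed(3)
    mm <- scoreMatrix(randGem(20, 10, seed = 8))
    holes <- matrix(runif(200) < 0.1, 20, 10)
    holes[rowSums(holes) == 10, ] <- FALSE
    mm[holes] <- NA
    gem2 <- makeGem(mm)
    imp <- imputeGeneMean(gem2)
    expect_false(anyNA(scoreMatrix(imp)))
    expect_identical(scoreMatrix(imp)[!holes], mm[!holes])
    expect_identical(scoreMatrix(imputeGeneMean(imp)), scoreMatrix(imp))
    # per-gene means of output equal per-gene means of observed input
    expect_equal(rowMeans(scoreMatrix(imp)),
                 rowMeans(mm, na.rm = TRUE), tolerance = 1e-12)
})

test_that("imputation refuses genes with no observed value", {
    m <- rbind(c(NA, NA, NA), c(1, 2, 3))
    expect_error(imputeGeneMean(makeGem(m)), "g01")
})

test_that("autoencoder preprocessing standardizes, clips and rescales", {
    gem <- makeGem(matrix(c(0, 5, 10), 1, 3))
    out <- scoreMatrix(aePreprocess(gem))
    expect_equal(as.numeric(out), c(-1, 0, 1), tolerance = 1e-12)
    # z-scores beyond the clip point saturate before min-max scaling
    m <- rbind(c(rep(0, 19), 10), rnorm(20))  # row 1 has a z of ~4.36
    z1 <- (m[1, ] - mean(m[1, ])) / sd(m[1, ])
    expect_gt(max(z1), 4)
    out2 <- scoreMatrix(aePreprocess(makeGem(m)))
    expect_identical(max(out2), 1)            # clipped value maps to the max
    expect_identical(sum(out2 == 1), 1L)
    # range contract and invariance to per-gene constants
    g3 <- randGem(15, 12, seed = 5)
    p3 <- scoreMatrix(aePreprocess(g3))
    expect_true(all(p3 >= -1 & p3 <= 1))
    expect_identical(min(p3), -1)
    expect_identical(max(p3), 1)
    shifted <- makeGem(scoreMatrix(g3) + seq_len(15))
    expect_equal(scoreMatrix(aePreprocess(shifted)), p3, tolerance = 1e-12)
    expect_error(aePreprocess(makeGem(rbind(c(1, 1, 1), c(1, 2, 3)))), "sd = 0")
})

writeMtxDir <- function(counts, genes, cells) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
    idx <- which(counts != 0, arr.ind = TRUE)
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 paste(nrow(counts), ncol(counts), nrow(idx)),
                 sprintf("%d %d %d", idx[, 1], idx[, 2],
                         counts[idx])),
               file.path(dir, "matrix.mtx"))
    writeLines(sprintf("ENSG%05d\t%s\tGene Expression",
                       seq_along(genes), genes),
               file.path(dir, "features.tsv"))
    writeLines(cells, file.path(dir, "barcodes.tsv"))
    dir
}

test_that("MTX reading and expression filters follow the stated rules", {
    set.seed(11)
    nGenes <- 30; nCells <- 60
    counts <- matrix(rpois(nGenes * nCells, 5), nGenes, nCells)
    genes <- c(sprintf("GENE%02d", seq_len(nGenes - 1)), "MT-ND1")
    cells <- sprintf("BC%03d", seq_len(nCells))
    # gene 1 nonzero in exactly 50 cells -> removed at threshold 50
    counts[1, ] <- 0; counts[1, 1:50] <- 1
    # gene 2 nonzero in 51 cells -> kept
    counts[2, ] <- 0; counts[2, 1:51] <- 1
    counts[nGenes, ] <- 1   # mito gene, ~3% of reads per cell: all kept
    dir <- writeMtxDir(counts, genes, cells)
    gem <- readCountsMtx(dir)
    expect_identical(dim(gem), c(30L, 60L))
    filt <- filterExpression(gem, minNonzeroCells = 50, minGenes = 3,
                             maxGenes = 1000, maxMitoPct = 7)
    expect_false("GENE01" %in% geneIds(filt))
    expect_true("GENE02" %in% geneIds(filt))
    expect_identical(length(sampleIds(filt)), 60L)
    # filtering twice equals filtering once on data with clear margins
    again <- filterExpression(filt, minNonzeroCells = 50, minGenes = 3,
                              maxGenes = 1000, maxMitoPct = 7)
    expect_identical(scoreMatrix(again), scoreMatrix(filt))
})

test_that("mito-percentage and gene-count cell filters remove cells", {
    counts <- matrix(5L, 20, 6,
                     dimnames = list(c(sprintf("G%02d", 1:18), "MT-A", "MT-B"),
                                     sprintf("c%d", 1:6)))
    counts[19:20, ] <- 1L          # baseline mito share 2/92 ~ 2.2%
    counts[3:20, 2] <- 0L          # cell 2 detects only 2 genes
    counts[19:20, 3] <- 30L        # cell 3 mito share = 60/150 = 40%
    filt <- filterExpression(makeGem(counts), minNonzeroCells = 0,
                             minGenes = 5, maxGenes = 100, maxMitoPct = 7)
    expect_identical(sampleIds(filt), c("c1", "c4", "c5", "c6"))
})

test_that("log-normalization matches its closed form", {
    counts <- matrix(c(10, 90, 0, 100), 2, 2,
                     dimnames = list(c("ga", "gb"), c("c1", "c2")))
    out <- scoreMatrix(logNormalize(makeGem(counts), scaleFactor = 1e4))
    expect_equal(out["ga", "c1"], log(1 + 10 * 1e4 / 100), tolerance = 1e-12)
    expect_equal(out["ga", "c1"], 6.9088, tolerance = 1e-4)
    expect_identical(out["ga", "c2"], 0)
})
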