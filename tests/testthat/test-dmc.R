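test_that("coverage parsing handles single lines, empty files and bad input", {
  dir <- tempfile(); dir.create(dir)
  sheet <- data.frame(sample = c("s1", "s2"), replicate = 1,
                      lineage = "ICM", methionine = c(10, 50))
  writeLines("chr1\t100\t100\t50.0\t5\t5", file.path(dir, "s1.cov"))
  file.create(file.path(dir, "s2.cov"))
  expect_warning(
    mce <- readBismarkCoverage(c(s1 = file.path(dir, "s1.cov"),
                                 s2 = file.path(dir, "s2.cov")), sheet),
    "empty")
  expect_equal(nrow(mce), 1)
  expect_equal(unname(covReads(mce)[1, "s1"]), 10L)
  expect_equal(unname(methReads(mce)[1, "s1"]), 5L)
  expect_equal(unname(covReads(mce)[1, "s2"]), 0L)

  writeLines(c("chr1\t100\t100\t50.0\t5\t5", "chr1\t200\tbroken"),
             file.path(dir, "bad.cov"))
  expect_error(
    readBismarkCoverage(c(s1 = file.path(dir, "bad.cov"),
                          s2 = file.path(dir, "s2.cov")),
                        sheet),
    "malformed.*2")
})

test_that("mixed chromosome-naming styles across samples are a hard error", {
  dir <- tempfile(); dir.create(dir)
  sheet <- data.frame(sample = c("s1", "s2"), replicate = 1,
                      lineage = "ICM", methionine = c(10, 50))
  writeLines("chr1\t100\t100\t50.0\t5\t5", file.path(dir, "s1.cov"))
  writeLines("1\t100\t100\t50.0\t5\t5", file.path(dir, "s2.cov"))
  expect_error(
    readBismarkCoverage(c(s1 = file.path(dir, "s1.cov"),
                          s2 = file.path(dir, "s2.cov")), sheet),
    "inconsistent chromosome naming")
})

test_that("unite/filter enforces mincov in every sample and masks variants", {
  mce <- countsExperiment(yA = c(5, 2, 8), nA = c(10, 4, 16),
                          yB = c(5, 2, 8), nB = c(10, 12, 16),
                          pos = c(100, 200, 300))
  kept <- uniteAndFilter(mce, mincov = 5)
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(kept)),
               c(100L, 300L))  # site 200 has coverage 4 in one sample
  masked <- uniteAndFilter(mce, mincov = 5,
                           variantMask = data.frame(chrom = "chr1", pos = 300))
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(masked)),
               100L)
  ident <- uniteAndFilter(mce, mincov = 5, variantMask = GenomicRanges::GRanges())
  expect_equal(nrow(ident), 2)
  # monotonicity in mincov
  ns <- vapply(c(1, 5, 11, 17), function(mc) nrow(uniteAndFilter(mce, mc)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("conversion QC computes rates, thresholds and degenerate cases", {
  mce <- countsExperiment(yA = c(10, 50), nA = c(1000, 1000),
                          yB = c(10, 50), nB = c(1000, 1000),
                          pos = c(5, 10))
  gr <- SummarizedExperiment::rowRanges(mce)
  GenomeInfoDb::seqlevels(gr) <- "lambda_spikein"
  SummarizedExperiment::rowRanges(mce) <- gr
  qc <- conversionQC(mce)
  expect_equal(qc$conversionRate, c(0.97, 0.97))
  expect_equal(qc$status, c("fail", "fail"))
  one <- conversionQC(mce[1, ])
  expect_equal(one$conversionRate, c(0.99, 0.99))
  expect_equal(one$status, c("pass", "pass"))
  none <- conversionQC(countsExperiment(5, 10, 5, 10))
  expect_equal(none$status, rep("not assessable", 2))
})

test_that("identical group counts give zero difference and p = 1", {
  mce <- countsExperiment(yA = 7, nA = 20, yB = 7, nB = 20)
  rec <- testDMC(mce, "methionine", "10", "50")
  expect_equal(rec$methDiff, 0)
  expect_equal(rec$pValue, 1)
})

test_that("single-replicate test equals the closed-form G-test and agrees with Fisher", {
  mce <- countsExperiment(yA = 30, nA = 40, yB = 10, nB = 40)
  rec <- testDMC(mce, "methionine", "10", "50")
  stat <- gtest2x2(30, 40, 10, 40)
  expect_equal(rec$pValue, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  fp <- fisher.test(matrix(c(30, 10, 10, 30), 2))$p.value
  expect_equal(rec$pValue < 0.05, fp < 0.05)
  expect_equal(rec$methDiff, 50)
  expect_equal(rec$direction, "gain")
})

test_that("deviance test matches a binomial GLM likelihood-ratio oracle", {
  set.seed(42)
  k <- 40
  yA1 <- rbinom(k, 30, 0.5); yA2 <- rbinom(k, 25, 0.5); yA3 <- rbinom(k, 35, 0.5)
  yB1 <- rbinom(k, 30, 0.3); yB2 <- rbinom(k, 28, 0.3); yB3 <- rbinom(k, 33, 0.3)
  dir <- tempfile(); dir.create(dir)
  sheet <- data.frame(sample = paste0("s", 1:6), replicate = rep(1:3, 2),
                      lineage = "ICM", methionine = rep(c(10, 50), each = 3))
  pos <- seq(100, by = 10, length.out = k)
  paths <- c()
  ys <- list(yA1, yA2, yA3, yB1, yB2, yB3)
  ns <- list(30, 25, 35, 30, 28, 33)
  for (i in 1:6)
    paths[paste0("s", i)] <- writeCov(
      data.frame(chrom = "chr1", pos = pos, m = ys[[i]], u = ns[[i]] - ys[[i]]),
      file.path(dir, paste0("s", i, ".cov")))
  mce <- readBismarkCoverage(paths, sheet)
  rec <- testDMC(mce, "methionine", "10", "50")
  for (i in seq_len(k)) {
    y <- vapply(ys, `[`, numeric(1), i)
    n <- unlist(ns)
    grp <- factor(rep(c("A", "B"), each = 3))
    fit <- glm(cbind(y, n - y) ~ grp, family = binomial())
    pOracle <- anova(fit, test = "LRT")[2, "Pr(>Chi)"]
    expect_equal(rec$pValue[i], pOracle, tolerance = 1e-10)
  }
})

test_that("swapping group labels negates differences and keeps p-values", {
  gen <- smallDataset()
  mce <- dropSpikein(smallExperiment())
  cd <- as.data.frame(SummarizedExperiment::colData(mce))
  sub <- uniteAndFilter(mce[, cd$lineage == "TE"], 5)
  ab <- testDMC(sub, "methionine", "10", "50")
  ba <- testDMC(sub, "methionine", "50", "10")
  expect_equal(ab$methDiff, -ba$methDiff, tolerance = 1e-12)
  expect_equal(ab$pValue, ba$pValue, tolerance = 1e-12)
  expect_equal(ab$qValue, ba$qValue, tolerance = 1e-12)
})

test_that("the per-CpG test holds its nominal size on a binomial null", {
  d <- rrbsDesign(seed = 303, nCpgSites = 2000, nGenes = 20,
                  nAffectedGenes = 0, nLineageSites = 0, overdispersion = 0,
                  nVariantPositions = 0, nSpikeinSites = 20)
  gen <- generateRRBS(d, tempfile())
  mce <- dropSpikein(readBismarkCoverage(gen$files[gen$sampleSheet$sample],
                                         gen$sampleSheet))
  cd <- as.data.frame(SummarizedExperiment::colData(mce))
  sub <- uniteAndFilter(mce[, cd$lineage == "ICM"], 5)
  rec <- testDMC(sub, "methionine", "10", "50")
  frac <- mean(rec$pValue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("DMC filtering applies strict effect cut and gene-context removal", {
  index <- smallIndex()
  gen <- smallDataset()
  # a promoter-resident position and an intergenic one, from the annotation
  prom <- index@promoters[1]
  promPos <- GenomicRanges::start(prom) +
    floor(GenomicRanges::width(prom) / 2)
  promChrom <- as.character(GenomicRanges::seqnames(prom))
  ann <- annotateSites(data.frame(chrom = "chr1", pos = 1:10), index)
  rec <- data.frame(
    chrom = c(promChrom, promChrom, "chr1"),
    pos = c(promPos, promPos + 1, 3),  # chr1:3 lies before any gene
    strand = "*",
    meanA = 0, meanB = 0,
    methDiff = c(20.0, 60, 60),
    pValue = 1e-9, qValue = 1e-9,
    direction = "gain")
  out <- filterDMC(rec, index)
  expect_equal(nrow(out), 1)             # exact 20 dropped; intergenic dropped
  expect_equal(out$pos, promPos + 1)
  expect_equal(out$geneFeature, "promoter")
  empty <- filterDMC(rec[0, ], index)
  expect_equal(nrow(empty), 0)
  # monotonicity: lowering maxQ never increases the DMC count
  gen <- smallDataset()
  mce <- dropSpikein(smallExperiment())
  cd <- as.data.frame(SummarizedExperiment::colData(mce))
  sub <- uniteAndFilter(mce[, cd$lineage == "ICM"], 5)
  full <- testDMC(sub, "methionine", "10", "50")
  ns <- vapply(c(0.2, 0.05, 0.01, 0.001),
               function(q) nrow(filterDMC(full, index, maxQ = q)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("direction summaries reproduce printed-table arithmetic", {
  s <- summarizeDirection(list(nGain = 2449, nLoss = 7542))
  expect_equal(s$nTotal, 9991)
  expect_equal(s$pctGain, 24.5)
  expect_equal(s$pctLoss, 75.5)
  one <- summarizeDirection(data.frame(direction = "gain"))
  expect_equal(one$pctGain, 100.0)
  expect_equal(one$pctLoss, 0.0)
  expect_equal(summarizeDirection(data.frame(direction = character(0)))$nTotal, 0)
})

test_that("transcript and gene counts are distinct-id counts", {
  rec <- data.frame(gene_id = c("g1", "g1"), transcript_id = c("g1.t1", "g1.t2"))
  expect_equal(countTranscriptsGenes(rec), list(nTranscripts = 2, nGenes = 1))
  expect_equal(countTranscriptsGenes(rec[0, ]),
               list(nTranscripts = 0, nGenes = 0))
})
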