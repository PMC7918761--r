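# shared fixtures, generated once per test run

.fixtureCache <- new.env(parent = emptyenv())

# small but fully featured synthetic dataset
smallDesign <- function(seed = 101, ...) {
  rrbsDesign(seed = seed, nCpgSites = 1500, nGenes = 30,
             nAffectedGenes = 8, nShiftedCpgs = 8, nClusterGenes = 4,
             nLineageSites = 60, nVariantPositions = 25,
             nSpikeinSites = 100, ...)
}

smallDataset <- function() {
  if (is.null(.fixtureCache$small)) {
    dir <- file.path(tempdir(), "met1c-small")
    .fixtureCache$small <- generateRRBS(smallDesign(), dir)
  }
  .fixtureCache$small
}

smallExperiment <- function() {
  if (is.null(.fixtureCache$mce)) {
    gen <- smallDataset()
    .fixtureCache$mce <- readBismarkCoverage(
      gen$files[gen$sampleSheet$sample], gen$sampleSheet)
  }
  .fixtureCache$mce
}

smallIndex <- function() {
  if (is.null(.fixtureCache$index)) {
    gen <- smallDataset()
    .fixtureCache$index <- buildFeatureIndex(gen$files[["gff"]],
                                             gen$files[["islands"]])
  }
  .fixtureCache$index
}

# write a tiny .cov file from a counts data.frame (chrom, pos, m, u)
writeCov <- function(df, path) {
  out <- data.frame(df$chrom, df$pos, df$pos,
                    round(100 * df$m / (df$m + df$u), 2), df$m, df$u)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# minimal 2-sample count experiment built directly (one sample per group)
countsExperiment <- function(yA, nA, yB, nB, pos = NULL) {
  k <- length(yA)
  if (is.null(pos)) pos <- seq(100, by = 50, length.out = k)
  dir <- tempfile(); dir.create(dir)
  sheet <- data.frame(sample = c("a1", "b1"), replicate = c(1, 1),
                      lineage = c("ICM", "ICM"), methionine = c(10, 50))
  fa <- writeCov(data.frame(chrom = "chr1", pos = pos, m = yA, u = nA - yA),
                 file.path(dir, "a1.cov"))
  fb <- writeCov(data.frame(chrom = "chr1", pos = pos, m = yB, u = nB - yB),
                 file.path(dir, "b1.cov"))
  readBismarkCoverage(c(a1 = fa, b1 = fb), sheet)
}

# simulate one gene's panel slice: per-CpG random intercepts plus fixed
# effects on the proportion scale
.simGene <- function(nCpg = 8, cpgSd = 0.1, interaction = 0.15,
                     lineageEff = 0, methEff = 0, resSd = 0.05,
                     base = 0.5, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(replicate = 1:3, lineage = c("TE", "ICM"),
                       methionine = c(50, 10), stringsAsFactors = FALSE)
  cpgInt <- rnorm(nCpg, 0, cpgSd)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    mu <- base + cpgInt +
      methEff * (cells$methionine[i] == 10) +
      lineageEff * (cells$lineage[i] == "ICM") +
      interaction * (cells$methionine[i] == 10 & cells$lineage[i] == "ICM")
    data.frame(gene_id = "g", cpg = paste0("c", seq_len(nCpg)),
               sample = paste0("s", i), replicate = cells$replicate[i],
               lineage = cells$lineage[i], methionine = cells$methionine[i],
               prop = pmin(pmax(mu + rnorm(nCpg, 0, resSd), 0), 1))
  }))
  rows
}

# closed-form 2x2 likelihood-ratio (G) statistic, written independently of
# the package implementation
gtest2x2 <- function(yA, nA, yB, nB) {
  ll <- function(y, n, p) {
    s <- 0
    if (y > 0) s <- s + y * log(p)
    if (n - y > 0) s <- s + (n - y) * log(1 - p)
    s
  }
  pA <- yA / nA; pB <- yB / nB; p0 <- (yA + yB) / (nA + nB)
  2 * (ll(yA, nA, pA) + ll(yB, nB, pB) - ll(yA, nA, p0) - ll(yB, nB, p0))
}
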