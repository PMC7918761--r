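#' Design of a synthetic RRBS experiment
#'
#' Describes a seeded synthetic dataset that emulates the structure of an
#' RRBS comparison of blastocyst lineages (ICM, TE) cultured at two added
#' methionine concentrations (10 and 50 uM), three replicates each: a small
#' multi-chromosome genome with non-overlapping gene models, CpG islands
#' around a subset of promoters, bimodal baseline CpG methylation, negative
#' binomial coverage, beta-binomial replicate noise, a treatment effect
#' concentrated in designated affected genes (a subset carrying >= 5 shifted
#' CpGs within 1 kb), an independent lineage effect at a disjoint CpG subset,
#' masked variant positions, and a fully unmethylated spike-in contig whose
#' apparent methylation equals the bisulfite conversion-failure rate.
#'
#' @param seed integer; mandatory, drives all randomness.
#' @param nChromosomes,chromLength genome shape (bp).
#' @param nGenes number of gene models (split over chromosomes).
#' @param promoterWindow promoter half-width around the TSS (bp).
#' @param nCpgSites number of genomic CpG sites (excluding spike-in).
#' @param coverageMean,coverageDispersion negative binomial mean and size for
#'   per-site coverage (truncated at >= 1).
#' @param baselineModes,baselineWeights low/high modes of the bimodal baseline
#'   methylation and their mixing weights.
#' @param nAffectedGenes genes carrying a methionine effect.
#' @param effectSize methionine effect in percentage points (10 vs 50 uM);
#'   applied in both lineages.
#' @param nShiftedCpgs shifted CpGs per affected gene.
#' @param nClusterGenes how many affected genes have their shifted CpGs
#'   packed within a 1 kb stretch (the remainder are dispersed so that no
#'   five fall within 1 kb).
#' @param propGainGenes fraction of affected genes gaining (rather than
#'   losing) methylation at 10 vs 50 uM.
#' @param nLineageSites CpGs (disjoint from affected genes) with an ICM-vs-TE
#'   shift of \code{lineageEffect} points at both concentrations.
#' @param lineageEffect lineage effect size (percentage points).
#' @param nVariantPositions CpG sites flagged as known variants (placed on
#'   unaffected sites; they must be masked, not tested).
#' @param overdispersion beta-binomial replicate-level overdispersion rho;
#'   0 gives pure binomial counts.
#' @param conversionFailureRate apparent methylation of the unmethylated
#'   spike-in contig.
#' @param nSpikeinSites CpG sites on the spike-in contig.
#' @return list of validated design parameters (class "rrbsDesign").
#' @export
rrbsDesign <- function(seed,
                       nChromosomes = 2,
                       chromLength = 1e6,
                       nGenes = 60,
                       promoterWindow = 1000,
                       nCpgSites = 6000,
                       coverageMean = 30,
                       coverageDispersion = 8,
                       baselineModes = c(low = 0.1, high = 0.9),
                       baselineWeights = c(0.4, 0.6),
                       nAffectedGenes = 20,
                       effectSize = 30,
                       nShiftedCpgs = 10,
                       nClusterGenes = 10,
                       propGainGenes = 0.2,
                       nLineageSites = 150,
                       lineageEffect = 30,
                       nVariantPositions = 50,
                       overdispersion = 0.01,
                       conversionFailureRate = 0.01,
                       nSpikeinSites = 200) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is mandatory")
  if (missing(nClusterGenes)) nClusterGenes <- min(nClusterGenes, nAffectedGenes)
  stopifnot(coverageMean >= 5, abs(effectSize) < 100, abs(effectSize) > 0 || nAffectedGenes == 0,
            nClusterGenes <= nAffectedGenes, nShiftedCpgs >= 1,
            overdispersion >= 0, overdispersion < 1,
            conversionFailureRate >= 0, conversionFailureRate <= 1,
            nCpgSites > 0, nGenes >= nAffectedGenes)
  d <- as.list(environment())
  class(d) <- "rrbsDesign"
  d
}

.sampleSheet <- function() {
  sheet <- expand.grid(replicate = 1:3, lineage = c("ICM", "TE"),
                       methionine = c(10, 50), stringsAsFactors = FALSE)
  sheet$sample <- sprintf("%s_%duM_rep%d", sheet$lineage, sheet$methionine,
                          sheet$replicate)
  sheet[, c("sample", "replicate", "lineage", "methionine")]
}

# beta-binomial draws: replicate-level proportion ~ Beta with mean p and
# intra-class correlation rho, then binomial reads
.rbetabinom <- function(n, size, p, rho) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  if (rho <= 0) return(stats::rbinom(n, size, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

# non-overlapping gene models with 2-5 exons; ~20% get a second transcript
.layoutGenes <- function(d) {
  genes <- list()
  perChrom <- ceiling(d$nGenes / d$nChromosomes)
  gid <- 0
  for (ch in seq_len(d$nChromosomes)) {
    pos <- 20000
    for (i in seq_len(perChrom)) {
      if (gid >= d$nGenes) break
      gid <- gid + 1
      len <- round(stats::runif(1, 6000, 15000))
      gap <- round(stats::runif(1, 6000, 12000))
      start <- pos
      end <- start + len - 1
      if (end > d$chromLength - 20000) break
      pos <- end + gap
      genes[[gid]] <- data.frame(
        gene_id = sprintf("gene%03d", gid),
        chrom = sprintf("chr%d", ch), start = start, end = end,
        strand = sample(c("+", "-"), 1))
    }
  }
  do.call(rbind, genes)
}

.layoutExons <- function(genes) {
  ex <- list(); tx <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    nTx <- if (stats::runif(1) < 0.2) 2L else 1L
    for (t in seq_len(nTx)) {
      txid <- sprintf("%s.t%d", g$gene_id, t)
      tx[[length(tx) + 1]] <- data.frame(
        transcript_id = txid, gene_id = g$gene_id, chrom = g$chrom,
        start = g$start, end = g$end, strand = g$strand)
      nEx <- sample(2:5, 1)
      # cut the gene span into 2*nEx-1 alternating exon/intron blocks
      cuts <- sort(sample(seq(g$start + 200, g$end - 200), 2 * nEx - 2))
      bounds <- c(g$start, cuts, g$end)
      for (e in seq_len(nEx)) {
        ex[[length(ex) + 1]] <- data.frame(
          transcript_id = txid, gene_id = g$gene_id, chrom = g$chrom,
          start = bounds[2 * e - 1], end = bounds[2 * e], strand = g$strand,
          exon = e)
      }
    }
  }
  list(transcripts = do.call(rbind, tx), exons = do.call(rbind, ex))
}

.layoutIslands <- function(genes, d) {
  # an island over every other gene's TSS plus a few intergenic ones
  idx <- seq(1, nrow(genes), by = 2)
  isl <- lapply(idx, function(i) {
    g <- genes[i, ]
    tss <- if (g$strand == "+") g$start else g$end
    half <- round(stats::runif(1, 250, 750))
    data.frame(chrom = g$chrom, start = max(1, tss - half), end = tss + half)
  })
  do.call(rbind, isl)
}

#' Write annotation files for a synthetic design
#'
#' Emits \code{genes.gff3} (gene/mRNA/exon features with
#' \code{##sequence-region} pragmas, including the spike-in contig),
#' \code{cpg_islands.bed}, and \code{sets.gmt} (gene sets constructed so that
#' the term \code{affected_set} contains every affected gene and random
#' control sets carry no signal).
#'
#' @param layout internal layout list (genes, transcripts, exons, islands).
#' @param d an [rrbsDesign()]. @param dir output directory.
#' @keywords internal
.writeAnnotationFiles <- function(layout, d, dir) {
  gff <- file.path(dir, "genes.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  for (ch in seq_len(d$nChromosomes))
    writeLines(sprintf("##sequence-region chr%d 1 %d", ch, as.integer(d$chromLength)), con)
  writeLines(sprintf("##sequence-region %s 1 48502", d$spikeinName %||% "lambda_spikein"), con)
  g <- layout$genes
  writeLines(sprintf("%s\tmet1C\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id), con)
  tx <- layout$transcripts
  writeLines(sprintf("%s\tmet1C\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     tx$chrom, tx$start, tx$end, tx$strand, tx$transcript_id,
                     tx$gene_id), con)
  ex <- layout$exons
  writeLines(sprintf("%s\tmet1C\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                     ex$chrom, ex$start, ex$end, ex$strand, ex$transcript_id,
                     ex$exon, ex$transcript_id), con)
  close(con)

  isl <- layout$islands
  utils::write.table(
    data.frame(isl$chrom, isl$start - 1L, isl$end,
               sprintf("CpG_island_%d", seq_len(nrow(isl)))),
    file.path(dir, "cpg_islands.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  affected <- layout$affectedGenes$gene_id
  others <- setdiff(layout$genes$gene_id, affected)
  sets <- list(affected_set = affected)
  nRand <- 10
  for (i in seq_len(nRand))
    sets[[sprintf("random_set_%02d", i)]] <-
      sample(others, min(length(others), sample(8:20, 1)))
  writeGMT(sets, file.path(dir, "sets.gmt"),
           descriptions = c("designed affected genes",
                            rep("random control set", nRand)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic RRBS dataset with ground truth
#'
#' Writes bismark-style \code{.cov} files for the 12-sample design
#' (3 replicates x \{ICM, TE\} x \{10, 50\} uM methionine), annotation
#' (GFF3 gene models, CpG-island BED, gene-set GMT), a variant-position BED,
#' a sample sheet, and \code{truth.json} recording the designed methylation
#' proportions and differentially methylated sites per contrast. Counts are
#' negative binomial coverage (truncated at >= 1) with beta-binomial
#' methylated reads around the group truth; the spike-in contig is drawn at
#' the conversion-failure rate. Byte-identical output for a given design.
#'
#' @param design an [rrbsDesign()].
#' @param dir output directory (created if needed).
#' @return (invisibly) a list: \code{dir}, \code{files} (named paths),
#'   \code{truth} (in-memory ground truth), \code{sampleSheet}.
#' @export
generateRRBS <- function(design, dir) {
  stopifnot(inherits(design, "rrbsDesign"))
  d <- design
  d$spikeinName <- "lambda_spikein"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(d$seed)

  genes <- .layoutGenes(d)
  txex <- .layoutExons(genes)
  islands <- .layoutIslands(genes, d)

  # --- CpG site placement --------------------------------------------------
  nProm <- round(0.10 * d$nCpgSites)
  nBody <- round(0.55 * d$nCpgSites)
  nInter <- d$nCpgSites - nProm - nBody
  pickInGene <- function(n, pad = 0) {
    i <- sample(nrow(genes), n, replace = TRUE)
    pos <- round(stats::runif(n, genes$start[i] + pad, genes$end[i] - pad))
    data.frame(chrom = genes$chrom[i], pos = pos)
  }
  promSites <- local({
    i <- sample(nrow(genes), nProm, replace = TRUE)
    tss <- ifelse(genes$strand[i] == "+", genes$start[i], genes$end[i])
    data.frame(chrom = genes$chrom[i],
               pos = round(tss + stats::runif(nProm, -d$promoterWindow,
                                              d$promoterWindow)))
  })
  bodySites <- pickInGene(nBody, pad = 50)
  interSites <- local({
    ch <- sample(d$nChromosomes, nInter, replace = TRUE)
    pos <- round(stats::runif(nInter, 1, d$chromLength))
    data.frame(chrom = sprintf("chr%d", ch), pos = pos)
  })
  sites <- rbind(promSites, bodySites, interSites)
  sites <- sites[sites$pos >= 1 & sites$pos <= d$chromLength, ]
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), ]

  # --- affected genes: shifted CpGs, clustered or dispersed ----------------
  affIdx <- sample(nrow(genes), d$nAffectedGenes)
  nGain <- round(d$propGainGenes * d$nAffectedGenes)
  direction <- rep(c("gain", "loss"),
                   c(nGain, d$nAffectedGenes - nGain))
  affected <- data.frame(gene_id = genes$gene_id[affIdx],
                         chrom = genes$chrom[affIdx],
                         start = genes$start[affIdx], end = genes$end[affIdx],
                         direction = direction,
                         clustered = seq_len(d$nAffectedGenes) <= d$nClusterGenes)
  affSites <- list()
  for (i in seq_len(nrow(affected))) {
    g <- affected[i, ]
    if (g$clustered) {
      anchor <- round(stats::runif(1, g$start + 500, g$end - 1500))
      pos <- sort(anchor + sample(0:800, d$nShiftedCpgs))
    } else {
      # spread with > 250 bp consecutive gaps so no 5 sites span <= 1 kb
      gaps <- round(stats::runif(d$nShiftedCpgs - 1, 300, 900))
      pos <- g$start + 300 + cumsum(c(0, gaps))
      pos <- pos[pos < g$end - 100]
    }
    affSites[[i]] <- data.frame(chrom = g$chrom, pos = pos,
                                gene_id = g$gene_id, direction = g$direction)
  }
  affSites <- do.call(rbind, affSites)
  # drop colliding baseline sites, then append the designed ones
  key <- function(x) paste(x$chrom, x$pos)
  sites <- sites[!key(sites) %in% key(affSites), ]
  sites <- rbind(sites, affSites[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  siteKey <- key(sites)
  affKey <- key(affSites)

  # --- true proportions per group ------------------------------------------
  nS <- nrow(sites)
  mode <- sample(c("low", "high"), nS, replace = TRUE, prob = d$baselineWeights)
  base <- ifelse(mode == "low", d$baselineModes[["low"]], d$baselineModes[["high"]])
  base <- pmin(pmax(base + stats::rnorm(nS, 0, 0.03), 0.02), 0.98)

  # affected sites start from the baseline modes themselves: loss genes sit
  # at the high mode and drop by the effect at 10 uM, gain genes at the low
  # mode and rise by it
  eff <- d$effectSize / 100
  p50 <- base; p10 <- base            # per-site truth at the two concentrations
  ia <- match(affKey, siteKey)
  gainA <- affSites$direction == "gain"
  lowM <- d$baselineModes[["low"]]; highM <- d$baselineModes[["high"]]
  p50[ia[gainA]] <- lowM; p10[ia[gainA]] <- min(lowM + eff, 0.98)
  p50[ia[!gainA]] <- highM; p10[ia[!gainA]] <- max(highM - eff, 0.02)

  # lineage effect at a disjoint subset (ICM hypermethylated there); kept
  # inside gene spans so the in-gene/promoter filter does not discard truth
  free <- setdiff(seq_len(nS), ia)
  inGene <- rep(FALSE, nS)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    inGene <- inGene | (sites$chrom == g$chrom & sites$pos >= g$start &
                        sites$pos <= g$end)
  }
  linIdx <- sort(sample(intersect(free, which(inGene)),
                        min(d$nLineageSites, sum(inGene[free]))))
  lshift <- d$lineageEffect / 100
  pICM10 <- p10; pTE10 <- p10; pICM50 <- p50; pTE50 <- p50
  pTE10[linIdx] <- pmax(pmin(p10[linIdx], 1 - lshift) , 0.02)
  pICM10[linIdx] <- pTE10[linIdx] + lshift
  pTE50[linIdx] <- pmax(pmin(p50[linIdx], 1 - lshift), 0.02)
  pICM50[linIdx] <- pTE50[linIdx] + lshift
  trueP <- cbind(ICM_10 = pICM10, TE_10 = pTE10, ICM_50 = pICM50, TE_50 = pTE50)

  # --- variant mask on unaffected, non-lineage sites ------------------------
  maskable <- setdiff(free, linIdx)
  varIdx <- sort(sample(maskable, min(d$nVariantPositions, length(maskable))))
  utils::write.table(
    data.frame(sites$chrom[varIdx], sites$pos[varIdx] - 1L, sites$pos[varIdx]),
    file.path(dir, "variants.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  # --- spike-in contig ------------------------------------------------------
  spikePos <- sort(sample(100:48400, d$nSpikeinSites))

  # --- per-sample counts ----------------------------------------------------
  sheet <- .sampleSheet()
  files <- character()
  for (s in seq_len(nrow(sheet))) {
    grp <- sprintf("%s_%d", sheet$lineage[s], sheet$methionine[s])
    p <- trueP[, grp]
    cov <- pmax(stats::rnbinom(nS, mu = d$coverageMean,
                               size = d$coverageDispersion), 1L)
    m <- .rbetabinom(nS, cov, p, d$overdispersion)
    covS <- pmax(stats::rnbinom(d$nSpikeinSites, mu = d$coverageMean,
                                size = d$coverageDispersion), 1L)
    mS <- stats::rbinom(d$nSpikeinSites, covS, d$conversionFailureRate)
    df <- data.frame(
      chrom = c(sites$chrom, rep(d$spikeinName, d$nSpikeinSites)),
      start = c(sites$pos, spikePos), end = c(sites$pos, spikePos),
      pct = round(100 * c(m, mS) / c(cov, covS), 2),
      m = c(m, mS), u = c(cov - m, covS - mS))
    f <- file.path(dir, paste0(sheet$sample[s], ".cov"))
    utils::write.table(df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[sheet$sample[s]] <- f
  }
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  layout <- list(genes = genes, transcripts = txex$transcripts,
                 exons = txex$exons, islands = islands,
                 affectedGenes = affected)
  .writeAnnotationFiles(layout, d, dir)

  truth <- list(
    sites = sites,
    trueP = trueP,
    affectedSites = data.frame(chrom = affSites$chrom, pos = affSites$pos,
                               gene_id = affSites$gene_id,
                               direction = affSites$direction),
    lineageSites = sites[linIdx, ],
    clusterGenes = affected$gene_id[affected$clustered],
    affectedGenes = affected$gene_id,
    variantPositions = sites[varIdx, ],
    spikeinContig = d$spikeinName,
    conversionFailureRate = d$conversionFailureRate)
  jsonlite::write_json(
    list(affectedSites = truth$affectedSites,
         lineageSites = truth$lineageSites,
         clusterGenes = truth$clusterGenes,
         affectedGenes = truth$affectedGenes,
         variantPositions = truth$variantPositions,
         spikeinContig = truth$spikeinContig,
         conversionFailureRate = truth$conversionFailureRate,
         seed = d$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  files <- c(files,
             gff = file.path(dir, "genes.gff3"),
             islands = file.path(dir, "cpg_islands.bed"),
             variants = file.path(dir, "variants.bed"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.json"),
             samples = file.path(dir, "samples.tsv"))
  invisible(list(dir = dir, files = files, truth = truth,
                 sampleSheet = sheet, design = d))
}
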