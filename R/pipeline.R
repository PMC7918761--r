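#' Run the full RRBS analysis pipeline on a synthetic design
#'
#' End-to-end orchestration: generate the dataset, import coverage files,
#' spike-in conversion QC, then for each of the four contrasts (methionine
#' 10 v 50 uM within each lineage; ICM v TE within each methionine
#' concentration) unite and filter, test, filter by q-value / effect size /
#' gene context, and summarise direction and transcript/gene counts. For the
#' two methionine contrasts it additionally selects genes with clustered
#' DMCs and runs hypergeometric gene-set enrichment, and (optionally) fits
#' the imprinted-gene mixed models. Writes per-stage TSVs plus a
#' machine-readable JSON summary including recovery metrics against the
#' generator's ground truth. Fully deterministic given the design seed.
#'
#' @param design an [rrbsDesign()].
#' @param outDir output directory; data are generated under
#'   \code{file.path(outDir, "data")}.
#' @param mincov,minDiff,maxQ,windowSize,minDmcs,enrichFdr stage thresholds
#'   (defaults 5, 20, 0.05, 1000, 5, 0.05).
#' @param imprintGenes "auto" (panel = affected genes plus a few unaffected
#'   controls, from the ground truth), NULL to skip, or a data.frame/TSV as
#'   for [buildImprintPanel()].
#' @return (invisibly) the summary list (also written as
#'   \code{run_summary.json}).
#' @export
runPipeline <- function(design, outDir, mincov = 5, minDiff = 20,
                        maxQ = 0.05, windowSize = 1000, minDmcs = 5,
                        enrichFdr = 0.05, imprintGenes = "auto") {
  stopifnot(mincov > 0, minDiff > 0, maxQ > 0, windowSize > 0, minDmcs > 0)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dataDir <- file.path(outDir, "data")
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf("[%6.1fs] %s",
                                          proc.time()[["elapsed"]] - t0, name))

  stage("generate")
  gen <- generateRRBS(design, dataDir)
  sheet <- gen$sampleSheet
  truth <- gen$truth

  stage("import")
  covPaths <- gen$files[sheet$sample]
  mce <- readBismarkCoverage(covPaths, sheet)

  stage("conversion QC")
  qc <- conversionQC(mce, truth$spikeinContig)
  mce <- dropSpikein(mce, truth$spikeinContig)

  stage("annotation index")
  index <- buildFeatureIndex(gen$files[["gff"]], gen$files[["islands"]])

  contrasts <- list(
    ICM_10v50 = list(subset = quote(lineage == "ICM"), group = "methionine",
                     a = "10", b = "50", truthKey = "affectedSites"),
    TE_10v50 = list(subset = quote(lineage == "TE"), group = "methionine",
                    a = "10", b = "50", truthKey = "affectedSites"),
    ICMvTE_10 = list(subset = quote(methionine == 10), group = "lineage",
                     a = "ICM", b = "TE", truthKey = "lineageSites"),
    ICMvTE_50 = list(subset = quote(methionine == 50), group = "lineage",
                     a = "ICM", b = "TE", truthKey = "lineageSites"))

  summary <- list(schema = "met1c-run-summary/1", seed = design$seed,
                  thresholds = list(mincov = mincov, minDiff = minDiff,
                                    maxQ = maxQ, windowSize = windowSize,
                                    minDmcs = minDmcs, enrichFdr = enrichFdr),
                  conversionQC = qc, contrasts = list(), enrichment = list())
  filteredByContrast <- list()
  universeByLineage <- list()

  for (cn in names(contrasts)) {
    stage(paste("contrast", cn))
    cc <- contrasts[[cn]]
    cd <- as.data.frame(colData(mce))
    sel <- eval(cc$subset, cd)
    sub <- uniteAndFilter(mce[, sel], mincov = mincov,
                          variantMask = gen$files[["variants"]])
    rec <- testDMC(sub, cc$group, cc$a, cc$b)
    flt <- filterDMC(rec, index, minDiff = minDiff, maxQ = maxQ)
    filteredByContrast[[cn]] <- flt
    utils::write.table(flt, file.path(outDir, paste0("dmc_", cn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dirSum <- summarizeDirection(flt)
    cnt <- countTranscriptsGenes(flt)
    truthSites <- truth[[cc$truthKey]]
    tKey <- paste(truthSites$chrom, truthSites$pos)
    dKey <- paste(flt$chrom, flt$pos)
    # sensitivity among truth sites that survived coverage filtering (the
    # caller's own misses); the fraction surviving is reported alongside
    tTested <- tKey[tKey %in% paste(rec$chrom, rec$pos)]
    sens <- if (length(tTested)) mean(tTested %in% dKey) else NA_real_
    truthTested <- if (length(tKey)) length(tTested) / length(tKey) else NA_real_
    fdr <- if (length(dKey)) mean(!dKey %in% tKey) else NA_real_
    # universe for enrichment: genes with >= 1 tested CpG in gene/promoter
    if (cc$group == "methionine") {
      annAll <- annotateSites(rec[, c("chrom", "pos")], index)
      lin <- cc$a; if (cc$group == "methionine") lin <- sub("_.*", "", cn)
      universeByLineage[[lin]] <-
        unique(annAll$gene_id[!is.na(annAll$gene_id)])
    }
    summary$contrasts[[cn]] <- list(
      nTested = nrow(rec), cpgCount = nrow(flt),
      nGain = dirSum$nGain, nLoss = dirSum$nLoss,
      pctGain = dirSum$pctGain, pctLoss = dirSum$pctLoss,
      transcripts = cnt$nTranscripts, genes = cnt$nGenes,
      sensitivity = sens, truthTestedFraction = truthTested,
      empiricalFDR = fdr)
  }

  gmt <- readGMT(gen$files[["gmt"]])
  for (lin in c("ICM", "TE")) {
    stage(paste("cluster/GSEA", lin))
    cn <- paste0(lin, "_10v50")
    cl <- clusterGenes(filteredByContrast[[cn]], windowSize, minDmcs)
    utils::write.table(cl, file.path(outDir, paste0("clusters_", lin, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    goi <- cl$gene_id[cl$qualifies]
    universe <- union(universeByLineage[[lin]], goi)
    enr <- if (length(goi))
      hypergeometricEnrichment(goi, universe, gmt)
    else data.frame()
    if (nrow(enr))
      utils::write.table(enr, file.path(outDir, paste0("enrichment_", lin, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    recovered <- intersect(goi, truth$clusterGenes)
    summary$enrichment[[lin]] <- list(
      nQualifyingGenes = length(goi),
      clusterGenesRecovered = length(recovered),
      clusterGenesDesigned = length(truth$clusterGenes),
      topTerms = if (nrow(enr)) utils::head(enr, 5) else NULL,
      affectedSetFdr = if (nrow(enr) && "affected_set" %in% enr$termId)
        enr$fdrBH[enr$termId == "affected_set"] else NA_real_)
  }

  if (identical(imprintGenes, "auto")) {
    aff <- truth$affectedSites
    gtab <- unique(data.frame(gene_id = aff$gene_id))
    # affected genes plus unaffected controls, spans from the annotation
    gb <- index@geneBodies
    ctrl <- setdiff(gb$gene_id, gtab$gene_id)[1:4]
    pick <- c(gtab$gene_id, ctrl)
    gsel <- gb[match(pick, gb$gene_id)]
    imprintGenes <- data.frame(
      gene_id = gsel$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gsel)),
      start = GenomicRanges::start(gsel), end = GenomicRanges::end(gsel))
  }
  if (!is.null(imprintGenes)) {
    stage("imprint mixed models")
    united <- uniteAndFilter(mce, mincov = mincov,
                             variantMask = gen$files[["variants"]])
    panel <- tryCatch(buildImprintPanel(united, imprintGenes),
                      error = function(e) NULL)
    if (!is.null(panel)) {
      fits <- fitImprintPanel(panel)
      rep <- imprintPanelReport(fits)
      utils::write.table(rep, file.path(outDir, "imprint_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$imprint <- rep
    }
  }

  stage("summary")
  jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(summary)
}
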