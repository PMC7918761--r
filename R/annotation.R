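#' Build a genomic feature index for CpG annotation
#'
#' Reads gene models from GFF3 (gene / mRNA / exon features) and CpG islands
#' from BED, and derives: strand-aware promoters (TSS - promoterUp to
#' TSS + promoterDown, 1-based inclusive), introns (transcript span minus
#' exons), and island shores (flanks of width \code{shoreWidth} on each side
#' of an island, clipped against islands and chromosome bounds so that
#' islands and shores are disjoint). Transcripts without a known strand are
#' skipped with a warning.
#'
#' @param gff path to a GFF3 file (or a GRanges as imported by rtracklayer).
#' @param islandsBed path to a CpG-island BED file (or GRanges); BED
#'   half-open 0-based coordinates are converted at import.
#' @param promoterUp,promoterDown promoter extent around the TSS (bp).
#' @param shoreWidth shore width (bp, default 2000).
#' @return A [FeatureIndex-class].
#' @export
buildFeatureIndex <- function(gff, islandsBed, promoterUp = 1000,
                              promoterDown = 1000, shoreWidth = 2000) {
  ann <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3") else gff
  type <- as.character(ann$type)
  tx <- ann[type %in% c("mRNA", "transcript")]
  if (!length(tx)) stop("no mRNA/transcript features in annotation")
  txStrand <- as.character(GenomicRanges::strand(tx))
  if (any(txStrand == "*")) {
    warning(sum(txStrand == "*"), " transcript(s) without strand skipped")
    tx <- tx[txStrand != "*"]
  }
  txId <- as.character(tx$ID)
  geneOfTx <- vapply(tx$Parent, function(p) as.character(p)[1], character(1))
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(transcript_id = txId,
                                               gene_id = geneOfTx)
  ex <- ann[type == "exon"]
  exParent <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
  keepEx <- exParent %in% txId
  ex <- ex[keepEx]; exParent <- exParent[keepEx]
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    transcript_id = exParent,
    gene_id = geneOfTx[match(exParent, txId)])

  tss <- GenomicRanges::resize(tx, width = 1, fix = "start")
  prom <- GenomicRanges::promoters(tx, upstream = promoterUp,
                                   downstream = promoterDown + 1)
  prom <- GenomicRanges::trim(prom)
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)

  # introns: per transcript, span minus exons
  exByTx <- GenomicRanges::split(ex, ex$transcript_id)
  spans <- unlist(range(exByTx))
  txMatch <- match(names(spans), txId)
  intrList <- GenomicRanges::psetdiff(spans, exByTx[names(spans)])
  intr <- unlist(intrList)
  intrTx <- rep(names(intrList), lengths(intrList))
  S4Vectors::mcols(intr) <- S4Vectors::DataFrame(
    transcript_id = intrTx, gene_id = geneOfTx[match(intrTx, txId)])
  names(intr) <- NULL

  genes <- ann[type == "gene"]
  if (length(genes))
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = as.character(genes$ID))

  isl <- if (is.character(islandsBed))
    rtracklayer::import(islandsBed, format = "BED") else islandsBed
  GenomicRanges::strand(isl) <- "*"
  if (length(isl)) {
    left <- GenomicRanges::flank(isl, shoreWidth, start = TRUE)
    right <- GenomicRanges::flank(isl, shoreWidth, start = FALSE)
    sh <- GenomicRanges::reduce(c(left, right))
    sh <- GenomicRanges::setdiff(sh, GenomicRanges::reduce(isl))
    sh <- GenomicRanges::trim(sh)
    GenomicRanges::start(sh) <- pmax(GenomicRanges::start(sh), 1L)
    shores <- sh[GenomicRanges::width(sh) > 0]
  } else shores <- GenomicRanges::GRanges()

  new("FeatureIndex", promoters = prom, exons = ex, introns = intr,
      geneBodies = genes, tss = tss, islands = isl, shores = shores,
      params = list(promoterUp = promoterUp, promoterDown = promoterDown,
                    shoreWidth = shoreWidth))
}

# assign each site to the nearest-TSS candidate among overlapping features
.assignFeature <- function(sitesGR, feat, tss) {
  hits <- GenomicRanges::findOverlaps(sitesGR, feat, ignore.strand = TRUE)
  if (!length(hits)) return(NULL)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  txOfFeat <- feat$transcript_id[s]
  tssPos <- GenomicRanges::start(tss)[match(txOfFeat, tss$transcript_id)]
  d <- abs(GenomicRanges::start(sitesGR)[q] - tssPos)
  ord <- order(q, d, txOfFeat)     # deterministic: nearest TSS, then id
  first <- !duplicated(q[ord])
  sel <- ord[first]
  data.frame(site = q[sel], transcript_id = txOfFeat[sel],
             gene_id = feat$gene_id[s][sel], stringsAsFactors = FALSE)
}

#' Annotate CpG sites with gene and CpG-island context
#'
#' Each site receives exactly one label per axis. Gene axis precedence:
#' promoter > exon > intron > intergenic; when a site lies in features of
#' several transcripts within a class, the transcript whose TSS is nearest
#' wins (ties broken by transcript id). CpG axis: island > shore > open_sea.
#'
#' @param sites data.frame with columns chrom, pos (1-based), or a GRanges.
#' @param index a [FeatureIndex-class].
#' @return data.frame: chrom, pos, geneFeature, cpgContext, gene_id,
#'   transcript_id (NA for intergenic sites).
#' @export
annotateSites <- function(sites, index) {
  if (is.data.frame(sites))
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, sites$pos))
  else gr <- sites
  n <- length(gr)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    geneFeature = rep("intergenic", n),
    cpgContext = rep("open_sea", n),
    gene_id = NA_character_, transcript_id = NA_character_,
    stringsAsFactors = FALSE)
  unset <- rep(TRUE, n)
  for (cls in c("promoter", "exon", "intron")) {
    feat <- switch(cls, promoter = index@promoters, exon = index@exons,
                   intron = index@introns)
    a <- .assignFeature(gr, feat, index@tss)
    if (is.null(a)) next
    take <- a[unset[a$site], , drop = FALSE]
    if (nrow(take)) {
      out$geneFeature[take$site] <- cls
      out$gene_id[take$site] <- take$gene_id
      out$transcript_id[take$site] <- take$transcript_id
      unset[take$site] <- FALSE
    }
  }
  inIsland <- IRanges::overlapsAny(gr, index@islands, ignore.strand = TRUE)
  inShore <- IRanges::overlapsAny(gr, index@shores, ignore.strand = TRUE)
  out$cpgContext[inShore] <- "shore"
  out$cpgContext[inIsland] <- "island"
  out
}

#' Percentage distribution of feature calls
#'
#' @param calls data.frame from [annotateSites()] (>= 1 row).
#' @return list of two named numeric vectors (percent, summing to 100 per
#'   axis): \code{geneFeature} and \code{cpgContext}.
#' @export
distributionSummary <- function(calls) {
  if (!nrow(calls)) stop("no feature calls to summarise")
  pct <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    stats::setNames(100 * as.numeric(tab) / length(x), levels)
  }
  list(geneFeature = pct(calls$geneFeature,
                         c("promoter", "exon", "intron", "intergenic")),
       cpgContext = pct(calls$cpgContext, c("island", "shore", "open_sea")))
}

#' @export
setMethod("show", "FeatureIndex", function(object) {
  cat("FeatureIndex:",
      length(unique(object@promoters$gene_id)), "genes,",
      length(object@promoters), "promoters,",
      length(object@exons), "exons,",
      length(object@islands), "islands,",
      length(object@shores), "shore intervals\n")
  cat("  promoter: TSS -", object@params$promoterUp, "/ +",
      object@params$promoterDown, "bp; shore width:",
      object@params$shoreWidth, "bp\n")
})
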