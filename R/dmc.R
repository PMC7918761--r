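#' Per-CpG differential methylation test
#'
#' For each CpG, fits a binomial proportion model of methylated/coverage on
#' group membership across the replicate samples and reports the 1-df
#' likelihood-ratio (deviance) chi-squared p-value. Because group membership
#' is the only covariate, the maximum-likelihood fitted proportions are the
#' group-pooled proportions, and the deviance statistic reduces to the
#' classical G-test on the pooled 2x2 table; \code{mode = "pearson"} gives
#' the Pearson chi-squared statistic on the same table instead. Group means
#' are pooled methylated / pooled coverage (percent), and q-values are
#' Benjamini-Hochberg over all tested sites.
#'
#' @param x a united [MethylCountExperiment-class] containing the samples of
#'   both groups.
#' @param group a factor/vector over samples with exactly two levels, or the
#'   name of a colData column (e.g. "methionine").
#' @param groupA,groupB the two levels to compare; the reported difference is
#'   groupA minus groupB (percentage points).
#' @param mode "deviance" (likelihood-ratio G-test, default) or "pearson".
#' @return data.frame of DMC records: chrom, pos, strand, meanA, meanB,
#'   methDiff, pValue, qValue, direction ("gain" if methDiff > 0, "loss" if
#'   < 0, NA at exactly 0). Sites with zero total coverage in either group
#'   are excluded, with the excluded count reported in a message.
#' @export
testDMC <- function(x, group, groupA = NULL, groupB = NULL,
                    mode = c("deviance", "pearson")) {
  mode <- match.arg(mode)
  if (is.character(group) && length(group) == 1)
    group <- colData(x)[[group]]
  group <- as.character(group)
  lv <- unique(group)
  if (is.null(groupA)) { groupA <- lv[1]; groupB <- lv[2] }
  groupA <- as.character(groupA); groupB <- as.character(groupB)
  inA <- group == groupA; inB <- group == groupB
  if (!any(inA) || !any(inB)) stop("each group needs >= 1 sample")
  M <- methReads(x); Cov <- covReads(x)
  yA <- rowSums(M[, inA, drop = FALSE]); nA <- rowSums(Cov[, inA, drop = FALSE])
  yB <- rowSums(M[, inB, drop = FALSE]); nB <- rowSums(Cov[, inB, drop = FALSE])
  ok <- nA > 0 & nB > 0
  if (any(!ok))
    message(sum(!ok), " site(s) excluded for zero group coverage")
  gr <- SummarizedExperiment::rowRanges(x)[ok]
  yA <- yA[ok]; nA <- nA[ok]; yB <- yB[ok]; nB <- nB[ok]
  pA <- yA / nA; pB <- yB / nB; p0 <- (yA + yB) / (nA + nB)
  if (mode == "deviance") {
    xlx <- function(y, n, p) {
      # y*log(p) + (n-y)*log(1-p) with 0*log(0) = 0
      t1 <- ifelse(y > 0, y * log(p), 0)
      t2 <- ifelse(n - y > 0, (n - y) * log(1 - p), 0)
      t1 + t2
    }
    stat <- 2 * (xlx(yA, nA, pA) + xlx(yB, nB, pB) -
                 xlx(yA, nA, p0) - xlx(yB, nB, p0))
    stat <- pmax(stat, 0)
  } else {
    o <- cbind(yA, nA - yA, yB, nB - yB)
    e <- cbind(nA * p0, nA * (1 - p0), nB * p0, nB * (1 - p0))
    stat <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
  }
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  diff <- 100 * (pA - pB)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    meanA = 100 * pA, meanB = 100 * pB, methDiff = diff,
    pValue = pval, qValue = stats::p.adjust(pval, method = "BH"),
    direction = ifelse(diff > 0, "gain", ifelse(diff < 0, "loss", NA)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter DMC records: significance, effect size, gene context
#'
#' Keeps records with q-value at most \code{maxQ}, absolute methylation
#' difference strictly greater than \code{minDiff} percentage points, and
#' located in a gene body or promoter (intergenic records are removed).
#' Feature annotation columns (geneFeature, cpgContext, gene_id,
#' transcript_id) are attached from the index.
#'
#' @param records data.frame from [testDMC()].
#' @param index a [FeatureIndex-class] from [buildFeatureIndex()].
#' @param minDiff minimum absolute difference, strict (default 20).
#' @param maxQ q-value threshold (default 0.05).
#' @return the filtered, annotated data.frame.
#' @export
filterDMC <- function(records, index, minDiff = 20, maxQ = 0.05) {
  if (!nrow(records)) {
    for (col in c("geneFeature", "cpgContext", "gene_id", "transcript_id"))
      records[[col]] <- character(0)
    return(records)
  }
  ann <- annotateSites(records[, c("chrom", "pos")], index)
  records$geneFeature <- ann$geneFeature
  records$cpgContext <- ann$cpgContext
  records$gene_id <- ann$gene_id
  records$transcript_id <- ann$transcript_id
  records[records$qValue <= maxQ &
          abs(records$methDiff) > minDiff &
          records$geneFeature != "intergenic", , drop = FALSE]
}

#' Direction-of-change summary for a set of DMCs
#'
#' Counts gains and losses of methylation and reports percentages to one
#' decimal, the format used for per-contrast summary tables.
#'
#' @param records data.frame with a \code{direction} column ("gain"/"loss"),
#'   or a list with counts \code{nGain} and \code{nLoss}.
#' @return list: nTotal, nGain, nLoss, pctGain, pctLoss.
#' @export
summarizeDirection <- function(records) {
  if (is.data.frame(records)) {
    nGain <- sum(records$direction == "gain", na.rm = TRUE)
    nLoss <- sum(records$direction == "loss", na.rm = TRUE)
  } else {
    nGain <- records$nGain; nLoss <- records$nLoss
  }
  nTotal <- nGain + nLoss
  if (nTotal == 0)
    return(list(nTotal = 0L, nGain = 0L, nLoss = 0L,
                pctGain = NA_real_, pctLoss = NA_real_))
  list(nTotal = nTotal, nGain = nGain, nLoss = nLoss,
       pctGain = round(100 * nGain / nTotal, 1),
       pctLoss = round(100 * nLoss / nTotal, 1))
}

#' Count distinct transcripts and genes harbouring at least one DMC
#'
#' @param records annotated DMC records (from [filterDMC()]).
#' @return list: nTranscripts, nGenes.
#' @export
countTranscriptsGenes <- function(records) {
  tx <- records$transcript_id
  g <- records$gene_id
  list(nTranscripts = length(unique(tx[!is.na(tx)])),
       nGenes = length(unique(g[!is.na(g)])))
}
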