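#' Assemble a per-gene CpG methylation panel for mixed-model analysis
#'
#' For each listed gene, collects the CpG sites falling within its interval
#' and the per-sample methylation proportion (methylated / coverage) at each
#' site, together with the design factors. Genes with fewer than two covered
#' CpGs are dropped with a warning (the per-CpG random intercept is not
#' estimable otherwise).
#'
#' @param x a united [MethylCountExperiment-class].
#' @param genes data.frame with columns gene_id, chrom, start, end (1-based
#'   inclusive), or a TSV path with those columns.
#' @return data.frame (long): gene_id, cpg, sample, replicate, lineage,
#'   methionine, prop.
#' @export
buildImprintPanel <- function(x, genes) {
  if (is.character(genes))
    genes <- utils::read.delim(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  gr <- SummarizedExperiment::rowRanges(x)
  M <- methReads(x); Cov <- covReads(x)
  cd <- as.data.frame(colData(x))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sel <- which(as.character(GenomicRanges::seqnames(gr)) == g$chrom &
                 GenomicRanges::start(gr) >= g$start &
                 GenomicRanges::start(gr) <= g$end)
    if (length(sel) < 2) {
      warning("gene ", g$gene_id, " has < 2 covered CpGs; dropped")
      next
    }
    cpg <- paste0(g$chrom, ":", GenomicRanges::start(gr)[sel])
    prop <- M[sel, , drop = FALSE] / Cov[sel, , drop = FALSE]
    rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id,
      cpg = rep(cpg, times = ncol(x)),
      sample = rep(colnames(x), each = length(sel)),
      replicate = rep(cd$replicate, each = length(sel)),
      lineage = rep(cd$lineage, each = length(sel)),
      methionine = rep(cd$methionine, each = length(sel)),
      prop = as.vector(prop), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no gene with >= 2 covered CpGs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' REML mixed model for one gene's CpG methylation
#'
#' Fits methylation proportion ~ replicate + methionine * lineage with a
#' random intercept per CpG, by REML (lme4). Fixed effects are reported with
#' Wald z-tests. A singular fit (zero CpG variance) falls back to ordinary
#' least squares, flagged in the result, in which case fixed effects equal
#' the OLS estimates. Reference levels: 50 uM methionine, TE lineage, so the
#' interaction coefficient is the extra 10 uM effect in the ICM. Cell means
#' are model predictions for the four methionine x lineage cells, averaged
#' over replicates.
#'
#' @param panelSlice rows of [buildImprintPanel()] output for one gene.
#' @param transform "identity" (default: raw proportions) or "arcsine"
#'   (asin(sqrt(p)) variance stabilisation).
#' @return list: gene_id, fixedEffects (data.frame term/estimate/se/z/p),
#'   varCpG, varResidual, cellMeans (named numeric, 4 cells), olsFallback.
#' @export
fitImprintGene <- function(panelSlice, transform = c("identity", "arcsine")) {
  transform <- match.arg(transform)
  d <- panelSlice
  stopifnot(length(unique(d$gene_id)) == 1)
  d$replicate <- factor(d$replicate)
  d$methionine <- factor(d$methionine, levels = c("50", "10"))
  d$lineage <- factor(d$lineage, levels = c("TE", "ICM"))
  if (any(is.na(d$methionine)) || any(is.na(d$lineage)))
    stop("unrecognised methionine/lineage levels")
  cells <- table(d$methionine, d$lineage)
  if (any(cells == 0)) stop("all four treatment cells must be represented")
  d$y <- if (transform == "arcsine") asin(sqrt(d$prop)) else d$prop

  fit <- suppressMessages(
    lme4::lmer(y ~ replicate + methionine * lineage + (1 | cpg),
               data = d, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-6)
  if (singular) {
    ols <- stats::lm(y ~ replicate + methionine * lineage, data = d)
    cf <- summary(ols)$coefficients
    est <- cf[, 1]; se <- cf[, 2]
    vc <- c(cpg = 0, resid = summary(ols)$sigma^2)
    predFun <- function(nd) stats::predict(ols, newdata = nd)
  } else {
    cf <- summary(fit)$coefficients
    est <- cf[, 1]; se <- cf[, 2]
    vcl <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(cpg = vcl$vcov[vcl$grp == "cpg"],
            resid = vcl$vcov[vcl$grp == "Residual"])
    predFun <- function(nd) stats::predict(fit, newdata = nd, re.form = NA)
  }
  z <- est / se
  fe <- data.frame(term = names(est), estimate = unname(est),
                   se = unname(se), z = unname(z),
                   p = 2 * stats::pnorm(-abs(unname(z))),
                   stringsAsFactors = FALSE, row.names = NULL)

  grid <- expand.grid(replicate = levels(d$replicate),
                      methionine = levels(d$methionine),
                      lineage = levels(d$lineage), stringsAsFactors = FALSE)
  grid$replicate <- factor(grid$replicate, levels = levels(d$replicate))
  grid$methionine <- factor(grid$methionine, levels = levels(d$methionine))
  grid$lineage <- factor(grid$lineage, levels = levels(d$lineage))
  grid$cpg <- d$cpg[1]
  grid$pred <- predFun(grid)
  cm <- tapply(grid$pred, paste(grid$lineage, grid$methionine, sep = "_"),
               mean)
  if (transform == "arcsine") cm <- sin(pmin(pmax(cm, 0), pi / 2))^2
  list(gene_id = d$gene_id[1], fixedEffects = fe,
       varCpG = unname(vc["cpg"]), varResidual = unname(vc["resid"]),
       cellMeans = cm, olsFallback = singular)
}

#' Fit the mixed model for every gene in a panel
#'
#' @param panel output of [buildImprintPanel()].
#' @param transform passed to [fitImprintGene()].
#' @return named list of per-gene results.
#' @export
fitImprintPanel <- function(panel, transform = "identity") {
  lapply(split(panel, panel$gene_id), fitImprintGene, transform = transform)
}

#' Significance flags and cell means across an imprinted-gene panel
#'
#' Flags, per gene, whether the lineage main effect, the methionine main
#' effect, or their interaction is significant at \code{alpha} (default
#' 0.001, a conservative reporting threshold), alongside the four cell
#' means, in a layout suitable for heat-map plotting.
#'
#' @param results list from [fitImprintPanel()] (>= 1 result).
#' @param alpha significance threshold on the Wald p-value.
#' @return data.frame: gene_id, the four cell-mean columns, p-values and
#'   logical flags for lineage, methionine and interaction, olsFallback.
#' @export
imprintPanelReport <- function(results, alpha = 0.001) {
  if (!length(results)) stop("no mixed-model results to report")
  rows <- lapply(results, function(r) {
    fe <- r$fixedEffects
    pOf <- function(term) {
      i <- which(fe$term == term)
      if (length(i)) fe$p[i] else NA_real_
    }
    pLin <- pOf("lineageICM")
    pMet <- pOf("methionine10")
    pInt <- pOf("methionine10:lineageICM")
    cm <- r$cellMeans
    data.frame(gene_id = r$gene_id,
               ICM_10 = cm[["ICM_10"]], ICM_50 = cm[["ICM_50"]],
               TE_10 = cm[["TE_10"]], TE_50 = cm[["TE_50"]],
               pLineage = pLin, pMethionine = pMet, pInteraction = pInt,
               sigLineage = !is.na(pLin) & pLin < alpha,
               sigMethionine = !is.na(pMet) & pMet < alpha,
               sigInteraction = !is.na(pInt) & pInt < alpha,
               olsFallback = r$olsFallback,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
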