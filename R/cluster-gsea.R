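#' Genes with clustered differentially methylated CpGs
#'
#' A gene qualifies when some window spanning at most \code{windowSize} bp
#' (inclusive, measured on the DMC positions themselves) contains at least
#' \code{minDmcs} of its DMCs: with sorted positions p, the gene qualifies
#' iff p[i + minDmcs - 1] - p[i] <= windowSize for some i. The reported best
#' window is the densest such stretch, ties broken by leftmost start.
#'
#' @param records annotated DMC records (from [filterDMC()]); rows without a
#'   gene assignment are ignored.
#' @param windowSize window span in bp (default 1000).
#' @param minDmcs minimum DMCs in a window (default 5).
#' @return data.frame: gene_id, nDmcsTotal, windowChrom, windowStart,
#'   windowEnd, windowCount, qualifies.
#' @export
clusterGenes <- function(records, windowSize = 1000, minDmcs = 5) {
  records <- records[!is.na(records$gene_id), , drop = FALSE]
  if (!nrow(records))
    return(data.frame(gene_id = character(), nDmcsTotal = integer(),
                      windowChrom = character(), windowStart = integer(),
                      windowEnd = integer(), windowCount = integer(),
                      qualifies = logical()))
  out <- lapply(split(records, records$gene_id), function(r) {
    pos <- sort(unique(r$pos))
    n <- length(pos)
    best <- c(count = 1L, start = pos[1], end = pos[1])
    j <- 1L
    for (i in seq_len(n)) {
      while (j < n && pos[j + 1] - pos[i] <= windowSize) j <- j + 1L
      cnt <- j - i + 1L
      if (cnt > best["count"])
        best <- c(count = cnt, start = pos[i], end = pos[j])
      if (j == n) break
    }
    data.frame(gene_id = r$gene_id[1], nDmcsTotal = n,
               windowChrom = r$chrom[1],
               windowStart = unname(best["start"]),
               windowEnd = unname(best["end"]),
               windowCount = unname(best["count"]),
               qualifies = unname(best["count"]) >= minDmcs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id), , drop = FALSE]
}

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in
#'   \code{attr(,"description")}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param descriptions optional character vector (recycled "NA" if absent).
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("NA", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, tests whether the genes of interest (GOI) are
#' over-represented relative to the universe: with N universe genes, K of
#' them in the term, n GOI and k GOI in the term, p = P(X >= k) under
#' Hypergeometric(N, K, n). Benjamini-Hochberg correction is applied across
#' all tested terms; terms with no universe gene (K = 0) are skipped and
#' counted in \code{attr(,"nSkipped")}.
#'
#' @param goi character vector of genes of interest; must be a subset of
#'   \code{universe} (offending ids are named in the error otherwise).
#' @param universe character vector of background genes (typically all genes
#'   with at least one tested CpG in gene body or promoter).
#' @param geneSets named list of character vectors (e.g. from [readGMT()]).
#' @return data.frame: termId, termName, k, K, n, N, pHypergeometric, fdrBH,
#'   ordered by p.
#' @export
hypergeometricEnrichment <- function(goi, universe, geneSets) {
  goi <- unique(goi); universe <- unique(universe)
  extra <- setdiff(goi, universe)
  if (length(extra))
    stop("genes of interest not in universe: ",
         paste(utils::head(extra, 10), collapse = ", "))
  N <- length(universe); n <- length(goi)
  desc <- attr(geneSets, "description")
  if (is.null(desc)) desc <- rep(NA_character_, length(geneSets))
  K <- vapply(geneSets, function(s) length(intersect(s, universe)), integer(1))
  keep <- K > 0
  nSkipped <- sum(!keep)
  k <- vapply(geneSets[keep], function(s) length(intersect(s, goi)), integer(1))
  Kk <- K[keep]
  p <- stats::phyper(k - 1, Kk, N - Kk, n, lower.tail = FALSE)
  res <- data.frame(termId = names(geneSets)[keep], termName = desc[keep],
                    k = k, K = Kk, n = n, N = N,
                    pHypergeometric = p,
                    fdrBH = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$pHypergeometric), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nSkipped") <- nSkipped
  res
}

#' Top pathways by number of differentially methylated genes of interest
#'
#' Among terms significant at \code{maxFdr}, ranks by the count k of genes
#' of interest in the term (descending), ties broken by FDR (ascending), and
#' returns the top \code{topN}.
#'
#' @param results data.frame from [hypergeometricEnrichment()].
#' @param topN how many terms to report (default 5).
#' @param maxFdr significance threshold (default 0.05).
#' @return the selected rows of \code{results}.
#' @export
rankPathways <- function(results, topN = 5, maxFdr = 0.05) {
  sig <- results[results$fdrBH <= maxFdr, , drop = FALSE]
  sig <- sig[order(-sig$k, sig$fdrBH), , drop = FALSE]
  utils::head(sig, topN)
}
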