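#' Read bismark-style coverage files into a MethylCountExperiment
#'
#' Parses \code{.cov} files (tab-separated: chrom, start, end, percent
#' methylation, count methylated, count unmethylated; 1-based, start = end)
#' and assembles the union of sites across samples into a
#' [MethylCountExperiment-class]. Sites absent from a sample get coverage 0
#' there. Malformed lines are reported with their line numbers; files whose
#' chromosome naming styles disagree (e.g. "chr1" vs "1") are a hard error.
#'
#' @param paths named character vector of file paths (names = sample ids), or
#'   unnamed (sample ids from file names).
#' @param sampleInfo data.frame with columns sample, replicate, lineage,
#'   methionine; rows matched to \code{names(paths)}.
#' @return A [MethylCountExperiment-class].
#' @export
readBismarkCoverage <- function(paths, sampleInfo) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.cov(\\.gz)?$", "", basename(paths))
  missingS <- setdiff(names(paths), sampleInfo$sample)
  if (length(missingS))
    stop("samples missing from sampleInfo: ", paste(missingS, collapse = ", "))
  tabs <- list()
  for (s in names(paths)) {
    raw <- readLines(paths[[s]])
    if (!length(raw)) {
      warning("empty coverage file for sample ", s)
      tabs[[s]] <- data.frame(chrom = character(), pos = integer(),
                              m = integer(), u = integer())
      next
    }
    parts <- strsplit(raw, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf != 6)
    if (!length(bad)) {
      mat <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
      m <- suppressWarnings(as.integer(mat[, 5]))
      u <- suppressWarnings(as.integer(mat[, 6]))
      pos <- suppressWarnings(as.integer(mat[, 2]))
      bad <- which(is.na(m) | is.na(u) | is.na(pos))
    }
    if (length(bad))
      stop("malformed line(s) in ", paths[[s]], ": ",
           paste(utils::head(bad, 10), collapse = ", "))
    tabs[[s]] <- data.frame(chrom = mat[, 1], pos = pos, m = m, u = u)
  }
  # chromosome-naming consistency: identical sets once a "chr" prefix is
  # stripped, but differing before, indicates mixed styles
  styles <- lapply(tabs, function(x) unique(x$chrom))
  norm <- lapply(styles, function(x) sub("^chr", "", x))
  for (i in seq_along(tabs)) for (j in seq_along(tabs)) {
    if (i < j && setequal(norm[[i]], norm[[j]]) &&
        !setequal(styles[[i]], styles[[j]]))
      stop("inconsistent chromosome naming between samples ",
           names(tabs)[i], " and ", names(tabs)[j])
  }
  keys <- lapply(tabs, function(x) paste(x$chrom, x$pos, sep = ":"))
  allKey <- unique(unlist(keys))
  split1 <- do.call(rbind, strsplit(allKey, ":", fixed = TRUE))
  ord <- order(split1[, 1], as.integer(split1[, 2]))
  allKey <- allKey[ord]
  chrom <- split1[ord, 1]; pos <- as.integer(split1[ord, 2])
  M <- Cov <- matrix(0L, nrow = length(allKey), ncol = length(tabs),
                     dimnames = list(NULL, names(tabs)))
  for (s in names(tabs)) {
    i <- match(keys[[s]], allKey)
    M[i, s] <- tabs[[s]]$m
    Cov[i, s] <- tabs[[s]]$m + tabs[[s]]$u
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos), strand = "*")
  cd <- sampleInfo[match(names(tabs), sampleInfo$sample), ]
  rownames(cd) <- cd$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(M = M, Cov = Cov), rowRanges = gr,
    colData = S4Vectors::DataFrame(cd))
  new("MethylCountExperiment", se)
}

#' @describeIn readBismarkCoverage Accessor for the methylated-count assay.
#' @param x a [MethylCountExperiment-class].
#' @export
methReads <- function(x) SummarizedExperiment::assay(x, "M")

#' @describeIn readBismarkCoverage Accessor for the coverage assay.
#' @export
covReads <- function(x) SummarizedExperiment::assay(x, "Cov")

#' Unite sites across samples and apply coverage/variant filters
#'
#' Retains CpG sites covered at least \code{mincov} times in every sample of
#' the object (call on the samples of the two compared groups) and not at a
#' masked variant position.
#'
#' @param x a [MethylCountExperiment-class].
#' @param mincov minimum per-sample coverage (default 5).
#' @param variantMask GRanges, or a data.frame with chrom/pos (1-based), or a
#'   BED file path; NULL for no masking.
#' @return the filtered [MethylCountExperiment-class].
#' @export
uniteAndFilter <- function(x, mincov = 5, variantMask = NULL) {
  keep <- rowSums(covReads(x) >= mincov) == ncol(x)
  if (!is.null(variantMask)) {
    if (is.character(variantMask))
      variantMask <- rtracklayer::import(variantMask, format = "BED")
    if (is.data.frame(variantMask))
      variantMask <- GenomicRanges::GRanges(
        variantMask$chrom, IRanges::IRanges(variantMask$pos, variantMask$pos))
    hit <- IRanges::overlapsAny(SummarizedExperiment::rowRanges(x), variantMask,
                                ignore.strand = TRUE)
    keep <- keep & !hit
  }
  x[keep, ]
}

#' Bisulfite-conversion QC from an unmethylated spike-in contig
#'
#' Per-sample conversion rate = unmethylated / total reads over sites of the
#' spike-in contig (fully unmethylated lambda DNA, so any apparent
#' methylation is conversion failure). Samples below \code{minRate} are
#' flagged, never silently dropped.
#'
#' @param x a [MethylCountExperiment-class].
#' @param spikeinContig contig name (default "lambda_spikein").
#' @param minRate pass threshold (default 0.98).
#' @return data.frame: sample, nSites, totalReads, conversionRate, status
#'   ("pass" / "fail" / "not assessable").
#' @export
conversionQC <- function(x, spikeinContig = "lambda_spikein", minRate = 0.98) {
  onSpike <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(x))) == spikeinContig
  out <- data.frame(sample = colnames(x), nSites = sum(onSpike),
                    totalReads = NA_real_, conversionRate = NA_real_,
                    status = "not assessable", stringsAsFactors = FALSE)
  if (!any(onSpike)) return(out)
  M <- methReads(x)[onSpike, , drop = FALSE]
  Cov <- covReads(x)[onSpike, , drop = FALSE]
  tot <- colSums(Cov)
  rate <- ifelse(tot > 0, (tot - colSums(M)) / tot, NA_real_)
  out$totalReads <- tot
  out$conversionRate <- rate
  out$status <- ifelse(is.na(rate), "not assessable",
                       ifelse(rate >= minRate, "pass", "fail"))
  out
}

#' Drop spike-in sites before differential analysis
#' @param x a [MethylCountExperiment-class].
#' @param spikeinContig contig name.
#' @export
dropSpikein <- function(x, spikeinContig = "lambda_spikein") {
  x[as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(x))) != spikeinContig, ]
}

#' @export
setMethod("show", "MethylCountExperiment", function(object) {
  cat("MethylCountExperiment:", nrow(object), "CpG sites x",
      ncol(object), "samples\n")
  cd <- colData(object)
  cat("  lineages:", paste(unique(cd$lineage), collapse = ", "),
      "| methionine (uM):", paste(unique(cd$methionine), collapse = ", "), "\n")
})
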