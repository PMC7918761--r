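#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowRanges
#' @importFrom GenomicRanges GRanges granges seqnames start end strand
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
NULL

.ENZYMES <- c("MATI", "MATII", "MATIII", "GNMT", "DNMT", "AHCY", "CBS",
              "MTR", "BHMT")
.METABOLITES <- c("met", "sam", "sah", "hcy")
.POOLS <- c("fivemthf", "betaine", "adenosine")

#' EnzymeProfile: kinetic constants and presence flags for the methionine cycle
#'
#' Holds, for each enzyme of the methionine cycle and transsulfuration branch
#' (MATI, MATII, MATIII, GNMT, a generic SAM-dependent DNA methyltransferase
#' DNMT, AHCY, CBS, MTR, BHMT), its maximal rate (vmax, uM/h), Michaelis and
#' modulation constants (uM), and a presence flag. Fixed substrate pools
#' (5-methyltetrahydrofolate, betaine, adenosine; uM) are treated as inputs,
#' not state variables. The \code{cellType} label records which preset the
#' profile was derived from ("hepatic": MATI/MATIII/BHMT present;
#' "follicular": MATII only, BHMT absent).
#'
#' @slot enzymes named list of per-enzyme parameter lists; each has a logical
#'   \code{present} plus numeric kinetic constants.
#' @slot pools named numeric vector with elements fivemthf, betaine, adenosine.
#' @slot cellType character scalar, informational.
#' @seealso [enzymeProfile()], [reactionFluxes()], [simulateMetCycle()]
#' @export
setClass("EnzymeProfile",
  representation(enzymes = "list", pools = "numeric", cellType = "character"))

setValidity("EnzymeProfile", function(object) {
  msg <- character()
  if (!identical(sort(names(object@enzymes)), sort(.ENZYMES)))
    msg <- c(msg, paste("enzymes must be exactly:", paste(.ENZYMES, collapse = ", ")))
  for (e in names(object@enzymes)) {
    p <- object@enzymes[[e]]
    if (!is.list(p) || is.null(p$present) || !is.logical(p$present))
      msg <- c(msg, paste0(e, ": missing logical 'present'"))
    num <- unlist(p[setdiff(names(p), "present")])
    if (any(!is.finite(num))) msg <- c(msg, paste0(e, ": non-finite parameter"))
    if (!is.null(p$vmax) && p$vmax < 0) msg <- c(msg, paste0(e, ": vmax must be >= 0"))
    kms <- unlist(p[grep("^km|^ki$|^ka$", names(p))])
    if (length(kms) && any(kms <= 0)) msg <- c(msg, paste0(e, ": km/ki/ka terms must be > 0"))
  }
  if (!all(.POOLS %in% names(object@pools)))
    msg <- c(msg, paste("pools must contain:", paste(.POOLS, collapse = ", ")))
  if (any(object@pools < 0)) msg <- c(msg, "pools must be >= 0")
  if (length(msg)) msg else TRUE
})

#' InputProtocol: methionine-input forcing for the kinetic model
#'
#' Describes the methionine influx V_in(t) (uM/h) driving the cycle:
#' \code{constant} (fixed at \code{baseline}); \code{step} (switches from
#' \code{baseline} to \code{stepTo} at \code{stepTime}); \code{sinusoid}
#' (baseline * (1 + relAmplitude * sin(2*pi*t/period))).
#'
#' @slot kind one of "constant", "step", "sinusoid".
#' @slot baseline,stepTo uM/h. @slot stepTime,period h.
#' @slot relAmplitude dimensionless fraction in [0, 1).
#' @export
setClass("InputProtocol",
  representation(kind = "character", baseline = "numeric", stepTo = "numeric",
                 stepTime = "numeric", relAmplitude = "numeric",
                 period = "numeric"))

setValidity("InputProtocol", function(object) {
  msg <- character()
  if (!object@kind %in% c("constant", "step", "sinusoid"))
    msg <- c(msg, "kind must be constant, step or sinusoid")
  if (object@baseline < 0) msg <- c(msg, "baseline must be >= 0")
  if (object@relAmplitude < 0 || object@relAmplitude >= 1)
    msg <- c(msg, "relAmplitude must be in [0, 1)")
  if (object@kind == "sinusoid" && object@period <= 0)
    msg <- c(msg, "period must be > 0 for sinusoid input")
  if (object@kind == "step" && (object@stepTo < 0 || object@stepTime < 0))
    msg <- c(msg, "stepTo and stepTime must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MetCycleTrajectory: a simulated time course of the methionine cycle
#'
#' @slot times numeric, strictly increasing (h).
#' @slot states matrix, one row per time, columns met, sam, sah, hcy (uM).
#' @slot fluxes matrix, one row per time, one column per reaction (uM/h).
#' @slot profile the [EnzymeProfile-class] used.
#' @slot input the [InputProtocol-class] used.
#' @export
setClass("MetCycleTrajectory",
  representation(times = "numeric", states = "matrix", fluxes = "matrix",
                 profile = "EnzymeProfile", input = "InputProtocol"))

setValidity("MetCycleTrajectory", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@states) != length(object@times) ||
      nrow(object@fluxes) != length(object@times))
    msg <- c(msg, "states/fluxes rows must match times")
  if (!identical(colnames(object@states), .METABOLITES))
    msg <- c(msg, "state columns must be met, sam, sah, hcy")
  if (length(msg)) msg else TRUE
})

#' MethylCountExperiment: per-CpG methylated/unmethylated read counts
#'
#' A \linkS4class{RangedSummarizedExperiment} with assays \code{M}
#' (methylated read count) and \code{Cov} (total coverage) over CpG sites
#' (width-1 ranges, 1-based) across samples. \code{colData} carries the
#' design factors \code{replicate}, \code{lineage} (ICM/TE) and
#' \code{methionine} (added concentration, uM).
#'
#' @export
setClass("MethylCountExperiment",
  contains = "RangedSummarizedExperiment")

setValidity("MethylCountExperiment", function(object) {
  msg <- character()
  if (!all(c("M", "Cov") %in% names(assays(object))))
    msg <- c(msg, "assays must contain 'M' and 'Cov'")
  else {
    M <- assay(object, "M"); Cov <- assay(object, "Cov")
    if (any(M < 0) || any(Cov < 0)) msg <- c(msg, "counts must be >= 0")
    if (any(M > Cov)) msg <- c(msg, "methylated count exceeds coverage")
  }
  need <- c("replicate", "lineage", "methionine")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' FeatureIndex: genomic feature intervals for CpG annotation
#'
#' Interval sets used to place CpG sites on two independent axes:
#' gene context (promoter > exon > intron > intergenic) and CpG context
#' (island > shore > open sea). All coordinates are 1-based inclusive
#' (converted from BED at import).
#'
#' @slot promoters,exons,introns,geneBodies,tss GRanges carrying gene_id and
#'   transcript_id metadata columns.
#' @slot islands,shores GRanges.
#' @slot params list: promoterUp, promoterDown, shoreWidth (bp).
#' @export
setClass("FeatureIndex",
  representation(promoters = "GRanges", exons = "GRanges", introns = "GRanges",
                 geneBodies = "GRanges", tss = "GRanges", islands = "GRanges",
                 shores = "GRanges", params = "list"))

setValidity("FeatureIndex", function(object) {
  msg <- character()
  if (length(object@islands) && length(object@shores) &&
      length(GenomicRanges::findOverlaps(object@islands, object@shores)) > 0)
    msg <- c(msg, "islands and shores must be disjoint")
  for (nm in c("promoterUp", "promoterDown", "shoreWidth"))
    if (is.null(object@params[[nm]])) msg <- c(msg, paste("params must contain", nm))
  if (length(msg)) msg else TRUE
})
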