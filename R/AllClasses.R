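#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start strand granges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' Locus-by-sample methylation count container
#'
#' `MethylomeSE` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with two integer assays, `meth` (methylated read count) and `coverage`
#' (total read count), one row per CpG locus and one column per sample.
#' Row ranges are width-1 `GRanges` at the plus-strand C of each CpG
#' (1-based, as usual for `GRanges`); the 0-based position used by the
#' text serialisation is available through [lociPositions()]. Missing
#' cells (locus not covered in a sample, or removed by a filter) are `NA`
#' in both assays.
#'
#' @slot .
#'   Inherits all slots from `RangedSummarizedExperiment`.
#' @export
setClass("MethylomeSE", contains = "RangedSummarizedExperiment")

setValidity("MethylomeSE", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("meth", "coverage") %in% an))
    msg <- c(msg, "assays must include 'meth' and 'coverage'")
  else {
    m <- assay(object, "meth")
    cv <- assay(object, "coverage")
    if (!identical(dim(m), dim(cv)))
      msg <- c(msg, "'meth' and 'coverage' dimensions differ")
    ok <- !(is.na(m) | is.na(cv))
    if (any(is.na(m) != is.na(cv)))
      msg <- c(msg, "'meth' and 'coverage' must be NA in the same cells")
    if (any(m[ok] < 0) || any(cv[ok] < m[ok]))
      msg <- c(msg, "counts must satisfy 0 <= meth <= coverage")
    key <- paste(as.character(seqnames(object)), start(object))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate loci are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylomeSE
#'
#' @param loci `GRanges` of width-1 plus-strand CpG positions, or a
#'   `data.frame` with columns `scaffold` and `pos` (0-based).
#' @param meth,coverage integer matrices, loci x samples; `NA` marks
#'   missing cells.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata
#'   (one row per column of `meth`); typically the output of
#'   [readSampleMetadata()].
#' @return A `MethylomeSE`.
#' @export
MethylomeSE <- function(loci, meth, coverage, sampleData = NULL) {
  if (is.data.frame(loci))
    loci <- GRanges(loci$scaffold, IRanges(loci$pos + 1L, width = 1L))
  meth <- as.matrix(meth); coverage <- as.matrix(coverage)
  storage.mode(meth) <- "integer"; storage.mode(coverage) <- "integer"
  if (is.null(sampleData)) {
    cn <- colnames(meth)
    if (is.null(cn)) cn <- paste0("S", seq_len(ncol(meth)))
    sampleData <- DataFrame(sample_id = cn, row.names = cn)
  } else {
    sampleData <- DataFrame(sampleData)
    if (is.null(rownames(sampleData)) && "sample_id" %in% colnames(sampleData))
      rownames(sampleData) <- sampleData$sample_id
  }
  colnames(meth) <- colnames(coverage) <- rownames(sampleData)
  se <- SummarizedExperiment(
    assays = list(meth = meth, coverage = coverage),
    rowRanges = loci, colData = sampleData)
  new("MethylomeSE", se)
}

#' @describeIn MethylomeSE methylated-count assay
#' @param x,object a `MethylomeSE`
#' @export
methCounts <- function(x) assay(x, "meth")

#' @describeIn MethylomeSE coverage assay
#' @export
covCounts <- function(x) assay(x, "coverage")

#' @describeIn MethylomeSE percent methylation (100 * meth / coverage);
#'   `NA` where coverage is zero or the cell is missing.
#' @export
percentMeth <- function(x) {
  m <- methCounts(x); cv <- covCounts(x)
  p <- 100 * m / cv
  p[!is.na(cv) & cv == 0L] <- NA_real_
  p
}

#' @describeIn MethylomeSE per-sample metadata as a plain data.frame
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @describeIn MethylomeSE per-locus 0-based positions of the plus-strand C
#' @export
lociPositions <- function(x) start(x) - 1L

#' @describeIn MethylomeSE locus keys "scaffold:pos" (pos 0-based)
#' @export
lociKeys <- function(x) paste0(as.character(seqnames(x)), ":", lociPositions(x))

setMethod("show", "MethylomeSE", function(object) {
  cv <- covCounts(object)
  cat("MethylomeSE with", nrow(object), "CpG loci x", ncol(object), "samples\n")
  miss <- mean(is.na(cv)) * 100
  cat(sprintf("  missing cells: %.1f%%; median coverage: %s\n",
              miss,
              if (all(is.na(cv))) "NA" else format(stats::median(cv, na.rm = TRUE))))
  if ("temperature" %in% colnames(colData(object)))
    cat("  temperatures:", paste(sort(unique(colData(object)$temperature)),
                                 collapse = ", "), "\n")
  invisible(object)
})

#' Sparse penalized methylation predictor
#'
#' Elastic-net model of a phenotype (hatchling sex, binomial family, or
#' past incubation temperature, gaussian family) from percent methylation
#' at a sparse set of CpG loci. Coefficients are stored on the original
#' percent-methylation scale so prediction needs no external objects.
#'
#' @slot family "binomial" or "gaussian".
#' @slot alpha elastic-net mixing parameter in [0, 1].
#' @slot lambda penalty selected by cross-validation.
#' @slot loci character keys ("scaffold:pos") of loci with nonzero
#'   coefficients.
#' @slot coefficients numeric, one per locus, percent-methylation scale.
#' @slot intercept numeric(1).
#' @slot classes for binomial models, the two phenotype levels; the
#'   predicted probability refers to the second.
#' @slot cvError cross-validated error at the selected lambda.
#' @slot seed integer seed used for fold assignment.
#' @export
setClass("SparsePredictor",
  representation(family = "character", alpha = "numeric", lambda = "numeric",
                 loci = "character", coefficients = "numeric",
                 intercept = "numeric", classes = "character",
                 cvError = "numeric", seed = "integer"))

setValidity("SparsePredictor", function(object) {
  msg <- character()
  if (!object@family %in% c("binomial", "gaussian"))
    msg <- c(msg, "family must be 'binomial' or 'gaussian'")
  if (length(object@loci) != length(object@coefficients))
    msg <- c(msg, "loci and coefficients lengths differ")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SparsePredictor", function(object) {
  cat("SparsePredictor (", object@family, ", alpha = ", object@alpha,
      ")\n  ", length(object@loci), " loci with nonzero coefficients; lambda = ",
      signif(object@lambda, 4), "\n", sep = "")
  invisible(object)
})
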