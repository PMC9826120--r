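#' Locus-retention filter configuration
#'
#' Defaults follow the standard RRBS processing chain: per-sample removal
#' of cells above the 99.9th coverage percentile (PCR-duplicate bias),
#' a minimum of 5 reads in at least half the samples of every
#' treatment group, removal of constitutively (>95% or <5%) methylated
#' loci, and removal of near-zero-variance loci under the caret
#' `nearZeroVar` defaults (frequency ratio 95/5, unique cut 10%).
#'
#' @param topCoveragePct percentile (0-100) above which per-sample
#'   coverage cells are discarded.
#' @param minCov minimum read coverage counted as "covered".
#' @param minPropPerGroup required fraction of covered samples per group.
#' @param hyperCut,hypoCut strict percent-methylation bounds for the
#'   constitutive filter.
#' @param freqCut,uniqueCut near-zero-variance thresholds.
#' @return a list with class `FilterConfig`.
#' @export
filterConfig <- function(topCoveragePct = 99.9, minCov = 5L,
                         minPropPerGroup = 0.5, hyperCut = 95,
                         hypoCut = 5, freqCut = 95 / 5, uniqueCut = 10) {
  stopifnot(minPropPerGroup > 0, minPropPerGroup <= 1, hypoCut < hyperCut)
  structure(list(topCoveragePct = topCoveragePct, minCov = minCov,
                 minPropPerGroup = minPropPerGroup, hyperCut = hyperCut,
                 hypoCut = hypoCut, freqCut = freqCut,
                 uniqueCut = uniqueCut), class = "FilterConfig")
}

.replaceCounts <- function(x, meth, cov) {
  SummarizedExperiment::assay(x, "meth", withDimnames = FALSE) <- meth
  SummarizedExperiment::assay(x, "coverage", withDimnames = FALSE) <- cov
  x
}

#' Remove extreme-coverage cells (PCR bias)
#'
#' Per sample, cells whose coverage strictly exceeds that sample's
#' `topCoveragePct` percentile (type-7 linear interpolation) are set
#' missing. The threshold is a quantile of the current data, so this
#' filter is meant to run exactly once, at the head of the pipeline;
#' re-applying it would trim the new tail again.
#'
#' @param x a [MethylomeSE].
#' @param topCoveragePct percentile, default 99.9.
#' @return filtered `MethylomeSE`.
#' @export
dropExtremeCoverage <- function(x, topCoveragePct = 99.9) {
  m <- methCounts(x); cv <- covCounts(x)
  for (j in seq_len(ncol(cv))) {
    col <- cv[, j]
    if (all(is.na(col))) next
    q <- stats::quantile(col, probs = topCoveragePct / 100,
                         na.rm = TRUE, type = 7, names = FALSE)
    kill <- !is.na(col) & col > q
    m[kill, j] <- NA_integer_
    cv[kill, j] <- NA_integer_
  }
  .replaceCounts(x, m, cv)
}

#' Require minimum coverage per treatment group
#'
#' A locus is retained iff in *every* treatment group the fraction of
#' that group's samples with coverage >= `minCov` is at least
#' `minPropPerGroup` (boundary inclusive).
#'
#' @param x a [MethylomeSE].
#' @param groups factor/character of treatment group per sample; by
#'   default the temperature-sex combination from `colData`.
#' @param minCov,minPropPerGroup thresholds (defaults 5 reads, 0.5).
#' @return filtered `MethylomeSE` (rows dropped).
#' @export
requireMinCoverage <- function(x, groups = NULL, minCov = 5L,
                               minPropPerGroup = 0.5) {
  if (is.null(groups)) {
    cd <- colData(x)
    groups <- paste(cd$temperature, cd$sex, sep = "_")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(x)) stop("one group per sample required")
  cv <- covCounts(x)
  ok <- rep(TRUE, nrow(x))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (!length(cols)) stop("group with zero samples: ", g)
    covered <- !is.na(cv[, cols, drop = FALSE]) &
      cv[, cols, drop = FALSE] >= minCov
    frac <- rowMeans(covered)
    ok <- ok & frac >= minPropPerGroup
  }
  x[ok, ]
}

#' Median-based coverage normalisation across samples
#'
#' Scales each sample's coverage toward the median of per-sample median
#' coverages: `f_s = median(median_s') / median_s`; coverage is scaled
#' and rounded (kept >= 1 where originally positive) and the methylated
#' count is scaled by the same factor and clamped to `[0, coverage]`,
#' preserving per-cell percent methylation within rounding.
#'
#' @param x a [MethylomeSE] with >= 2 samples.
#' @return normalised `MethylomeSE`.
#' @export
normalizeCoverage <- function(x) {
  if (ncol(x) < 2L) stop("need >= 2 samples to normalise")
  m <- methCounts(x); cv <- covCounts(x)
  meds <- apply(cv, 2, stats::median, na.rm = TRUE)
  if (anyNA(meds)) stop("sample with all-missing coverage")
  target <- stats::median(meds)
  f <- target / meds
  for (j in seq_len(ncol(cv))) {
    col <- cv[, j]
    obs <- !is.na(col)
    newcov <- as.integer(round(col[obs] * f[j]))
    newcov[col[obs] > 0L & newcov < 1L] <- 1L
    newm <- as.integer(round(m[obs, j] * f[j]))
    newm <- pmin(pmax(newm, 0L), newcov)
    cv[obs, j] <- newcov
    m[obs, j] <- newm
  }
  .replaceCounts(x, m, cv)
}

#' Remove constitutively hyper- and hypomethylated loci
#'
#' A locus is removed iff its percent methylation is strictly above
#' `hyperCut` in all non-missing samples, or strictly below `hypoCut`
#' in all non-missing samples.
#'
#' @param x a [MethylomeSE].
#' @param hyperCut,hypoCut percent bounds (defaults 95 and 5).
#' @return filtered `MethylomeSE`.
#' @export
removeConstitutive <- function(x, hyperCut = 95, hypoCut = 5) {
  p <- percentMeth(x)
  anyObs <- rowSums(!is.na(p)) > 0L
  allHyper <- anyObs &
    rowSums(!is.na(p) & p <= hyperCut) == 0L
  allHypo <- anyObs &
    rowSums(!is.na(p) & p >= hypoCut) == 0L
  x[!(allHyper | allHypo), ]
}

#' Remove near-zero-variance loci
#'
#' caret-style `nearZeroVar` rule on percent methylation (values
#' compared at 4-decimal precision): a locus is removed iff the ratio of
#' the most frequent value to the second most frequent is >= `freqCut`
#' *and* the percentage of distinct values over samples is <=
#' `uniqueCut`. All-constant loci are removed unconditionally.
#'
#' @param x a [MethylomeSE].
#' @param freqCut,uniqueCut thresholds (defaults 19 and 10).
#' @return filtered `MethylomeSE`.
#' @export
removeNearZeroVariance <- function(x, freqCut = 95 / 5, uniqueCut = 10) {
  p <- percentMeth(x)
  nzv <- vapply(seq_len(nrow(p)), function(i) {
    v <- round(p[i, !is.na(p[i, ])], 4)
    if (!length(v)) return(FALSE)
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1L) return(TRUE)
    freqRatio <- tab[[1L]] / tab[[2L]]
    pctUnique <- 100 * length(tab) / length(v)
    freqRatio >= freqCut && pctUnique <= uniqueCut
  }, logical(1))
  x[!nzv, ]
}

#' Run the full locus-retention pipeline with an audit log
#'
#' Applies, in order: extreme-coverage removal, per-group minimum
#' coverage, coverage normalisation, constitutive-methylation removal,
#' near-zero-variance removal.
#'
#' @param x a [MethylomeSE].
#' @param config a [filterConfig()].
#' @param groups optional treatment-group vector (see
#'   [requireMinCoverage()]).
#' @return list with `matrix` (the filtered `MethylomeSE`) and `log`
#'   (data.frame of loci counts after each stage).
#' @export
filterSites <- function(x, config = filterConfig(), groups = NULL) {
  log <- data.frame(stage = "input", loci = nrow(x))
  rec <- function(stage, x) log <<- rbind(log, data.frame(stage = stage,
                                                          loci = nrow(x)))
  x <- dropExtremeCoverage(x, config$topCoveragePct); rec("extreme_coverage", x)
  x <- requireMinCoverage(x, groups, config$minCov, config$minPropPerGroup)
  rec("min_coverage", x)
  x <- normalizeCoverage(x); rec("normalize", x)
  x <- removeConstitutive(x, config$hyperCut, config$hypoCut)
  rec("constitutive", x)
  x <- removeNearZeroVariance(x, config$freqCut, config$uniqueCut)
  rec("near_zero_variance", x)
  list(matrix = x, log = log)
}
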