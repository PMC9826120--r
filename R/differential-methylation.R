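#' Per-CpG overdispersion-corrected logistic-regression test
#'
#' For each locus, methylated counts are modelled as binomial with
#' `logit(p_j) = b0 + b1 * group_j`. With a single binary covariate the
#' maximum-likelihood fit is the pair of pooled per-group proportions,
#' so the likelihood-ratio statistic `2 (l_full - l_null)` has a closed
#' form. Overdispersion is estimated from the Pearson residuals of the
#' full model, `phi = sum(r^2) / (J - 2)` over the `J` samples with
#' positive coverage, and the statistic is divided by `max(phi, 1)`
#' (correction applied only when overdispersed). The default reference
#' distribution is F(1, J - 2), which accounts for the sampling noise
#' of the plug-in dispersion estimate at the study's sample sizes; a
#' chi-squared(1) reference is available via `reference = "chisq"`.
#' The methylation difference is the difference of pooled per-group
#' percentages (coverage-weighted), group A minus group B.
#'
#' @param meth,coverage numeric matrices (loci x samples) or vectors for
#'   a single locus; `NA` marks missing cells.
#' @param groupA,groupB column indices (or logical masks) of the two
#'   groups.
#' @param reference `"F"` (default) or `"chisq"` reference distribution
#'   for the corrected statistic.
#' @return data.frame with one row per locus: `meth_diff`, `lrt`,
#'   `phi`, `df2` (denominator df, `J - 2`), `p`. Loci where either
#'   group has no positive coverage get `NA` results.
#' @export
dmLogisticTest <- function(meth, coverage, groupA, groupB,
                           reference = c("F", "chisq")) {
  reference <- match.arg(reference)
  if (is.null(dim(meth))) { meth <- rbind(meth); coverage <- rbind(coverage) }
  mA <- meth[, groupA, drop = FALSE]; nA <- coverage[, groupA, drop = FALSE]
  mB <- meth[, groupB, drop = FALSE]; nB <- coverage[, groupB, drop = FALSE]
  zero <- function(x) { x[is.na(x)] <- 0; x }
  mA <- zero(mA); mB <- zero(mB); nA <- zero(nA); nB <- zero(nB)
  MA <- rowSums(mA); NA_ <- rowSums(nA)
  MB <- rowSums(mB); NB <- rowSums(nB)
  ok <- NA_ > 0 & NB > 0
  pA <- ifelse(NA_ > 0, MA / NA_, NA)
  pB <- ifelse(NB > 0, MB / NB, NA)
  p0 <- (MA + MB) / (NA_ + NB)
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  llg <- function(M, N, p) xlogy(M, p) + xlogy(N - M, 1 - p)
  llFull <- llg(MA, NA_, pA) + llg(MB, NB, pB)
  llNull <- llg(MA, NA_, p0) + llg(MB, NB, p0)
  lrt <- pmax(2 * (llFull - llNull), 0)
  # Pearson residuals of the full (two-proportion) model
  pres2 <- function(m, n, p) {
    e <- n * p
    v <- n * p * (1 - p)
    r2 <- (m - e)^2 / v
    r2[!is.finite(r2)] <- 0    # v = 0 implies m = e exactly
    r2
  }
  sumR2 <- rowSums(pres2(mA, nA, pA)) + rowSums(pres2(mB, nB, pB))
  J <- rowSums(nA > 0) + rowSums(nB > 0)
  phi <- ifelse(J > 2, sumR2 / (J - 2), 1)
  stat <- lrt / pmax(phi, 1)
  df2 <- pmax(J - 2, 1)
  p <- if (reference == "F")
    stats::pf(stat, df1 = 1, df2 = df2, lower.tail = FALSE)
  else
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  res <- data.frame(meth_diff = 100 * (pA - pB), lrt = lrt,
                    phi = phi, df2 = df2, p = p)
  res[!ok, ] <- NA
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: q values
#' are capped at 1 and invariant to input permutation.
#'
#' @param p numeric vector of p-values in [0, 1] (`NA` passed through).
#' @return vector of q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.contrastNames <- c("FvM", "F34.5vM34.5", "30v33.5", "30v34.5", "33.5v34.5")

#' Run the five study contrasts
#'
#' Two sex contrasts (all females vs all males; 34.5-degree females vs
#' 34.5-degree males) and the three pairwise temperature contrasts
#' (30v33.5, 30v34.5, 33.5v34.5), each tested per locus with
#' [dmLogisticTest()] and BH-adjusted within the contrast. The
#' methylation difference of a temperature contrast is
#' (lower temperature - higher temperature).
#'
#' @param x a filtered [MethylomeSE] whose `colData` carries `sex` and
#'   `temperature`.
#' @return named list of data.frames, one per contrast, each with
#'   columns `scaffold`, `pos`, `meth_diff`, `lrt`, `phi`, `p`, `q`.
#' @export
runContrasts <- function(x, reference = c("F", "chisq")) {
  reference <- match.arg(reference)
  cd <- colData(x)
  defs <- list(
    "FvM" = list(A = cd$sex == "F", B = cd$sex == "M"),
    "F34.5vM34.5" = list(A = cd$sex == "F" & cd$temperature == 34.5,
                         B = cd$sex == "M" & cd$temperature == 34.5),
    "30v33.5" = list(A = cd$temperature == 30, B = cd$temperature == 33.5),
    "30v34.5" = list(A = cd$temperature == 30, B = cd$temperature == 34.5),
    "33.5v34.5" = list(A = cd$temperature == 33.5, B = cd$temperature == 34.5))
  m <- methCounts(x); cv <- covCounts(x)
  out <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    if (!any(d$A) || !any(d$B))
      stop("contrast ", nm, " has an empty side")
    res <- dmLogisticTest(m, cv, d$A, d$B, reference = reference)
    res$q <- bhAdjust(res$p)
    cbind(data.frame(scaffold = as.character(seqnames(x)),
                     pos = lociPositions(x)), res)
  })
  names(out) <- names(defs)
  out
}

#' Pairwise temperature contrasts for an arbitrary design
#'
#' Used for data sets without sex assignments (e.g., embryonic gonads):
#' all pairwise contrasts among the temperatures present, BH-adjusted
#' within each contrast. Differences are (lower - higher) temperature.
#'
#' @param x a filtered [MethylomeSE] with `temperature` in `colData`.
#' @return named list of contrast data.frames as in [runContrasts()].
#' @export
runTemperatureContrasts <- function(x, reference = c("F", "chisq")) {
  reference <- match.arg(reference)
  temps <- sort(unique(colData(x)$temperature))
  if (length(temps) < 2L) stop("need >= 2 temperatures")
  pairs <- utils::combn(temps, 2, simplify = FALSE)
  m <- methCounts(x); cv <- covCounts(x)
  out <- lapply(pairs, function(pr) {
    A <- colData(x)$temperature == pr[1]
    B <- colData(x)$temperature == pr[2]
    res <- dmLogisticTest(m, cv, A, B, reference = reference)
    res$q <- bhAdjust(res$p)
    cbind(data.frame(scaffold = as.character(seqnames(x)),
                     pos = lociPositions(x)), res)
  })
  names(out) <- vapply(pairs, function(pr) paste0(pr[1], "v", pr[2]),
                       character(1))
  out
}

#' Classify differentially methylated cytosines with sex precedence
#'
#' A locus significant (q < `fdr`, strict) in the all-female-vs-all-male
#' contrast is "universal sex-associated"; significant in that or in the
#' 34.5-degree within-temperature sex contrast makes it
#' "sex-associated"; significance in any pairwise temperature contrast
#' makes it "temperature-associated" *only if* it is not sex-associated
#' (sex takes precedence, so the temperature set is purged of
#' sex-confounded loci). Sex direction comes from the sign of the
#' female-minus-male difference; temperature direction is positive when
#' methylation increases with temperature (taken from the most
#' significant temperature contrast).
#'
#' @param contrasts output of [runContrasts()].
#' @param fdr significance threshold on q (default 0.1).
#' @return data.frame with `scaffold`, `pos`, `class` (universal_sex /
#'   sex / temperature / none), `direction`, `universal` (logical), and
#'   `source_contrasts` (comma-separated significant contrasts).
#' @export
classifyDMCs <- function(contrasts, fdr = 0.1) {
  stopifnot(all(.contrastNames %in% names(contrasts)))
  base <- contrasts[["FvM"]][c("scaffold", "pos")]
  sig <- vapply(.contrastNames, function(nm) {
    q <- contrasts[[nm]]$q
    !is.na(q) & q < fdr
  }, logical(nrow(base)))
  if (is.null(dim(sig))) sig <- rbind(sig)
  colnames(sig) <- .contrastNames
  tempNames <- c("30v33.5", "30v34.5", "33.5v34.5")
  universal <- sig[, "FvM"]
  isSex <- universal | sig[, "F34.5vM34.5"]
  anyTemp <- rowSums(sig[, tempNames, drop = FALSE]) > 0
  isTemp <- anyTemp & !isSex
  class <- ifelse(universal, "universal_sex",
                  ifelse(isSex, "sex",
                         ifelse(isTemp, "temperature", "none")))
  direction <- rep("n/a", nrow(base))
  # sex: the FvM difference where that contrast is significant, else the
  # 34.5-only contrast
  sexDiff <- ifelse(sig[, "FvM"], contrasts[["FvM"]]$meth_diff,
                    contrasts[["F34.5vM34.5"]]$meth_diff)
  direction[isSex] <- ifelse(sexDiff[isSex] > 0, "female_biased", "male_biased")
  # temperature: sign of (low - high) difference in the most significant
  # temperature contrast; negative difference = increases with temperature
  if (any(isTemp)) {
    qs <- vapply(tempNames, function(nm) contrasts[[nm]]$q,
                 numeric(nrow(base)))
    if (is.null(dim(qs))) qs <- rbind(qs)
    qs[!sig[, tempNames, drop = FALSE]] <- NA
    diffBest <- vapply(which(isTemp), function(i) {
      best <- tempNames[which.min(qs[i, ])]
      contrasts[[best]]$meth_diff[i]
    }, numeric(1))
    direction[isTemp] <- ifelse(diffBest < 0,
                                "positive_with_temperature",
                                "negative_with_temperature")
  }
  src <- apply(sig, 1, function(s) paste(.contrastNames[s], collapse = ","))
  data.frame(base, class = class, direction = direction,
             universal = universal, source_contrasts = src)
}

#' DMC rate as a percentage of covered loci
#'
#' @param nDmc number of differentially methylated cytosines.
#' @param nCovered number of covered (analysed) cytosines, > 0.
#' @return `100 * nDmc / nCovered`, reported at 2 significant figures.
#' @export
summarizeDmcRate <- function(nDmc, nCovered) {
  stopifnot(nCovered > 0, nDmc >= 0, nDmc <= nCovered)
  signif(100 * nDmc / nCovered, 2)
}

#' K-nearest-neighbour imputation of a percent-methylation matrix
#'
#' For each locus with missing cells, the `k` nearest loci (Euclidean
#' distance over jointly observed samples, averaged per shared sample)
#' that are observed in the missing sample supply the value, imputed as
#' the mean of the neighbours' values in that sample. Loci missing in
#' more than `rowmax` of samples fall back to the locus mean. With
#' fewer than `k` usable neighbours all available ones are used, with a
#' warning.
#'
#' @param pm numeric matrix (loci x samples), `NA` for missing.
#' @param k number of neighbours (default 10).
#' @param rowmax missingness fraction above which the locus-mean
#'   fallback is used (default 0.5).
#' @return complete numeric matrix.
#' @export
knnImpute <- function(pm, k = 10L, rowmax = 0.5) {
  pm <- as.matrix(pm)
  missRow <- which(rowSums(is.na(pm)) > 0L)
  if (!length(missRow)) return(pm)
  if (any(rowSums(!is.na(pm)) == 0L))
    stop("locus with no observed values cannot be imputed")
  obs <- !is.na(pm)
  x0 <- pm; x0[!obs] <- 0
  m <- obs * 1
  # mean squared difference over jointly observed samples, via BLAS
  sq <- x0^2
  shared <- tcrossprod(m)
  d2 <- (sq %*% t(m)) + (m %*% t(sq)) - 2 * tcrossprod(x0)
  d2 <- d2 / shared          # NaN where no shared samples
  out <- pm
  rmean <- rowSums(x0) / rowSums(m)
  warned <- FALSE
  for (i in missRow) {
    cols <- which(!obs[i, ])
    if (mean(!obs[i, ]) > rowmax) {
      out[i, cols] <- rmean[i]
      next
    }
    for (j in cols) {
      cand <- which(obs[, j])
      cand <- cand[cand != i & is.finite(d2[i, cand])]
      if (!length(cand)) { out[i, j] <- rmean[i]; next }
      if (length(cand) < k && !warned) {
        warning("fewer than k usable neighbours for some loci; using all")
        warned <- TRUE
      }
      nb <- cand[order(d2[i, cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(pm[nb, j])
    }
  }
  out
}

#' Genome-wide Spearman correlation screen
#'
#' Rank correlation (average ranks for ties) of each locus's percent
#' methylation with a per-sample covariate (incubation temperature or a
#' plasma hormone level), p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df, BH-adjusted.
#'
#' @param pm complete (imputed) percent matrix, loci x samples.
#' @param covariate numeric per-sample covariate.
#' @return data.frame with `rho`, `p`, `q`; constant loci (or a
#'   constant covariate) yield `NA` and are flagged in `flagged`.
#' @export
spearmanScreen <- function(pm, covariate) {
  pm <- as.matrix(pm)
  if (anyNA(pm)) stop("impute the matrix before the correlation screen")
  if (length(covariate) != ncol(pm)) stop("covariate per sample required")
  n <- ncol(pm)
  rc <- rank(covariate)
  rcC <- rc - mean(rc)
  denC <- sqrt(sum(rcC^2))
  R <- t(apply(pm, 1, rank))
  Rc <- R - rowMeans(R)
  den <- sqrt(rowSums(Rc^2)) * denC
  rho <- as.numeric(Rc %*% rcC) / den
  rho[den == 0] <- NA
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  data.frame(rho = rho, p = p, q = bhAdjust(p), flagged = is.na(rho))
}

#' Compare absolute correlation strength between two locus sets
#'
#' Two-sided Mann-Whitney U test on |rho| (exact when both sets have
#' <= 8 values and no ties; tie-corrected normal approximation
#' otherwise), e.g. temperature-associated DMCs vs all other loci.
#'
#' @param rhosA,rhosB numeric vectors of correlation coefficients.
#' @return list with `U` and `p`.
#' @export
compareAbsRho <- function(rhosA, rhosB) {
  a <- abs(rhosA[!is.na(rhosA)]); b <- abs(rhosB[!is.na(rhosB)])
  if (!length(a) || !length(b)) stop("both sets must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = length(a) <= 8 && length(b) <= 8))
  list(U = unname(wt$statistic), p = wt$p.value)
}
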