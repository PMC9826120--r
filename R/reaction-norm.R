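#' Observed sex ratio as percent male
#'
#' @param nMale,nTotal male and total hatchling counts, `nTotal > 0`.
#' @return `100 * nMale / nTotal`, rounded to one decimal.
#' @export
observedSexRatio <- function(nMale, nTotal) {
  if (any(nTotal <= 0)) stop("nTotal must be positive")
  stopifnot(all(nMale >= 0), all(nMale <= nTotal))
  round(100 * nMale / nTotal, 1)
}

#' Fit the quadratic-logistic temperature-by-sex-ratio reaction norm
#'
#' Grouped-binomial logistic regression of the proportion of male
#' hatchlings on incubation temperature with a quadratic term:
#' `logit(P(male)) = b0 + b1 T + b2 T^2`. Temperature is centered
#' before fitting for numerical stability and the coefficients are
#' back-transformed to the raw scale. In crocodilians the ratio is
#' unimodal in temperature (female-male-female), so `b2 < 0` and the
#' vertex `-b1 / (2 b2)` estimates the male-maximising temperature.
#'
#' @param records data.frame with columns `temperature`, `n_male`,
#'   `n_total` (one row per incubation treatment; rows are weighted by
#'   `n_total` through the binomial likelihood).
#' @return list with `b0`, `b1`, `b2`, `vcov` (raw-scale), `vertex`,
#'   `fit` (the `glm` object), `separation` flag, and
#'   `predict(t, level)` returning fitted percent male with a Wald
#'   confidence band computed on the link scale.
#' @export
fitReactionNorm <- function(records) {
  stopifnot(all(c("temperature", "n_male", "n_total") %in% colnames(records)))
  if (length(unique(records$temperature)) < 3L)
    stop("need >= 3 distinct temperatures for a quadratic fit")
  tbar <- mean(records$temperature)
  tc <- records$temperature - tbar
  fit <- suppressWarnings(
    stats::glm(cbind(n_male, n_total - n_male) ~ tc + I(tc^2),
               family = stats::binomial(), data = cbind(records, tc = tc)))
  separation <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separation)
    warning("degenerate or separated fit; coefficients unreliable")
  cc <- stats::coef(fit)                     # c0 + c1 tc + c2 tc^2
  b2 <- cc[[3L]]
  b1 <- cc[[2L]] - 2 * b2 * tbar
  b0 <- cc[[1L]] - cc[[2L]] * tbar + b2 * tbar^2
  # delta-method transform of the covariance to the raw scale
  J <- rbind(c(1, -tbar, tbar^2), c(0, 1, -2 * tbar), c(0, 0, 1))
  V <- J %*% stats::vcov(fit) %*% t(J)
  vertex <- if (b2 != 0) -b1 / (2 * b2) else NA_real_
  predictFun <- function(t, level = 0.95) {
    tcNew <- t - tbar
    X <- cbind(1, tcNew, tcNew^2)
    eta <- drop(X %*% cc)
    se <- sqrt(rowSums((X %*% stats::vcov(fit)) * X))
    z <- stats::qnorm(1 - (1 - level) / 2)
    data.frame(temperature = t,
               percent_male = 100 * stats::plogis(eta),
               lower = 100 * stats::plogis(eta - z * se),
               upper = 100 * stats::plogis(eta + z * se))
  }
  list(b0 = b0, b1 = b1, b2 = b2, vcov = V, vertex = vertex,
       fit = fit, separation = separation, predict = predictFun)
}
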