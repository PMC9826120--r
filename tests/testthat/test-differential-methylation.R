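test_that("identical groups give zero difference and p = 1", {
  m <- matrix(c(5L, 6L, 5L, 6L), nrow = 1)
  n <- matrix(10L, 1, 4)
  res <- dmLogisticTest(m, n, 1:2, 3:4)
  expect_equal(res$meth_diff, 0)
  expect_equal(res$lrt, 0)
  expect_equal(res$p, 1)
})

test_that("the closed-form fit matches the numerical likelihood oracle", {
  # worked example: A m=(9,8)/10, B m=(1,2)/10 -> pooled 85% vs 15%
  m <- matrix(c(9L, 8L, 1L, 2L), nrow = 1)
  n <- matrix(10L, 1, 4)
  res <- dmLogisticTest(m, n, 1:2, 3:4)
  expect_equal(res$meth_diff, 70)
  orc <- oracleDmTest(m[1, ], n[1, ], c(1, 1, 0, 0))
  expect_equal(res$lrt, orc$lrt, tolerance = 1e-6)
  expect_equal(res$phi, orc$phi, tolerance = 1e-6)
  expect_equal(res$p, orc$p, tolerance = 1e-6)
  # random fixtures
  set.seed(21)
  for (rep in 1:10) {
    J <- sample(6:12, 1)
    grp <- rep(c(1, 0), length.out = J)
    nv <- rpois(J, 25) + 5L
    mv <- rbinom(J, nv, ifelse(grp == 1, 0.6, 0.35))
    res <- dmLogisticTest(rbind(mv), rbind(nv), grp == 1, grp == 0)
    orc <- oracleDmTest(mv, nv, grp)
    expect_equal(res$lrt, orc$lrt, tolerance = 1e-5)
    expect_equal(res$p, orc$p, tolerance = 1e-5)
  }
})

test_that("groups without coverage yield missing results", {
  m <- matrix(c(0L, 0L, 3L, 4L), nrow = 1)
  n <- matrix(c(0L, 0L, 10L, 10L), nrow = 1)
  res <- dmLogisticTest(m, n, 1:2, 3:4)
  expect_true(is.na(res$p))
})

test_that("overdispersed counts raise phi and the corrected p", {
  set.seed(3)
  J <- 16
  grp <- rep(c(TRUE, FALSE), each = 8)
  n <- matrix(rpois(40 * J, 30) + 1L, 40, J)
  pcell <- matrix(rbeta(40 * J, 0.5 * (1 - 0.2) / 0.2,
                        0.5 * (1 - 0.2) / 0.2), 40, J)
  m <- matrix(rbinom(40 * J, n, pcell), 40, J)
  res <- dmLogisticTest(m, n, grp, !grp)
  expect_true(median(res$phi) > 1)
  raw <- pf(res$lrt, 1, res$df2, lower.tail = FALSE)
  expect_true(all(res$p >= raw - 1e-12))
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bhAdjust(1), 1)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("contrasts use the right samples and flag planted effects", {
  cfg <- simulationConfig(seed = 31, nLoci = 600, fracSexDmc = 1 / 600,
                          fracTempDmc = 0, sexEffectLogit = 4,
                          frac345Specific = 0)
  sim <- simulateMethylomes(cfg)
  fl <- filterSites(sim$se)
  ct <- runContrasts(fl$matrix)
  planted <- sim$truth[sim$truth$class == "sex", ]
  key <- paste0(planted$scaffold, ":", planted$pos)
  fvm <- ct[["FvM"]]
  idx <- match(key, paste0(fvm$scaffold, ":", fvm$pos))
  # the single planted locus has the smallest q in FvM
  expect_equal(which.min(fvm$q), idx)
  # the within-34.5 contrast uses only the 8 samples at 34.5 C
  expect_equal(max(ct[["F34.5vM34.5"]]$df2, na.rm = TRUE), 6)
  # empty side errors
  md <- sim$metadata
  blood30 <- fl$matrix[, md$sample_id[md$temperature == 30]]
  expect_error(runContrasts(blood30), "empty side")
})

test_that("permuted labels give a near-nominal false-positive rate", {
  cfg <- simulationConfig(seed = 37, nLoci = 4000, fracSexDmc = 0,
                          fracTempDmc = 0, betaBinomialRho = 0,
                          clutchSdLogit = 0)
  sim <- simulateMethylomes(cfg)
  fl <- filterSites(sim$se)
  x <- fl$matrix
  set.seed(99)
  perm <- sample(ncol(x))
  res <- dmLogisticTest(methCounts(x), covCounts(x),
                        perm[1:12], perm[13:24])
  fp <- mean(res$p < 0.05, na.rm = TRUE)
  se3 <- 3 * sqrt(0.05 * 0.95 / sum(!is.na(res$p)))
  # discreteness plus the dispersion floor make the test mildly
  # conservative; the rate must sit at or just below nominal
  expect_lt(fp, 0.05 + se3)
  expect_gt(fp, 0.02)
})

test_that("DMC classification applies sex precedence", {
  mk <- function(qs, diffs = rep(10, 3)) {
    data.frame(scaffold = "s", pos = 1:3, meth_diff = diffs,
               lrt = 1, phi = 1, df2 = 10, p = qs, q = qs)
  }
  ct <- list(
    "FvM" = mk(c(0.01, 0.5, 0.5), c(12, 0, 0)),
    "F34.5vM34.5" = mk(c(0.5, 0.01, 0.5), c(0, -15, 0)),
    "30v33.5" = mk(c(0.5, 0.5, 0.5)),
    "30v34.5" = mk(c(0.01, 0.5, 0.5), c(-20, 0, 0)),
    "33.5v34.5" = mk(c(0.5, 0.5, 0.5)))
  lab <- classifyDMCs(ct)
  # locus 1: significant in FvM and 30v34.5 -> sex precedence
  expect_equal(lab$class[1], "universal_sex")
  expect_equal(lab$direction[1], "female_biased")
  # locus 2: only in the 34.5 contrast -> sex but not universal
  expect_equal(lab$class[2], "sex")
  expect_false(lab$universal[2])
  expect_equal(lab$direction[2], "male_biased")
  # locus 3: significant nowhere
  expect_equal(lab$class[3], "none")
  # temperature direction: increases with temperature = negative
  # (low - high) difference
  ct2 <- ct
  ct2[["FvM"]]$q[1] <- 0.5
  lab2 <- classifyDMCs(ct2)
  expect_equal(lab2$class[1], "temperature")
  expect_equal(lab2$direction[1], "positive_with_temperature")
})

test_that("DMC rates reproduce the published arithmetic", {
  expect_equal(summarizeDmcRate(120, 462236), 0.026)
  expect_equal(summarizeDmcRate(707, 462236), 0.15)
  expect_equal(summarizeDmcRate(0, 1000), 0)
  expect_error(summarizeDmcRate(1, 0))
})

test_that("KNN imputation fills cells from nearest loci", {
  pm <- matrix(c(10, 20, 30,
                 11, 21, 31,
                 80, 85, 90), 3, 3, byrow = TRUE)
  expect_identical(knnImpute(pm), pm)   # complete: unchanged
  pm2 <- pm
  pm2[1, 3] <- NA
  # nearest locus over shared samples is locus 2 -> value 31
  expect_equal(knnImpute(pm2, k = 1)[1, 3], 31)
  # k = 2: mean of loci 2 and 3 in that sample
  expect_equal(knnImpute(pm2, k = 2)[1, 3], mean(c(31, 90)))
  # fewer usable neighbours than k: all available used, with warning
  expect_warning(out <- knnImpute(pm2, k = 5), "fewer than k")
  expect_equal(out[1, 3], mean(c(31, 90)))
  # high-missingness locus falls back to its own mean
  pm3 <- rbind(c(50, NA, NA, NA), matrix(60, 5, 4))
  out3 <- knnImpute(pm3, k = 1, rowmax = 0.5)
  expect_equal(out3[1, 2], 50)
})

test_that("imputed values stay within the neighbour range", {
  set.seed(17)
  pm <- matrix(runif(400, 0, 100), 50, 8)
  pm[sample(400, 40)] <- NA
  pm[1, ] <- runif(8, 0, 100)  # keep at least one complete locus
  out <- suppressWarnings(knnImpute(pm, k = 5, rowmax = 1))
  expect_false(anyNA(out))
  miss <- which(is.na(pm), arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    j <- miss[r, 2]
    obs <- pm[!is.na(pm[, j]), j]
    expect_gte(out[miss[r, 1], j], min(obs))
    expect_lte(out[miss[r, 1], j], max(obs))
  }
})

test_that("the Spearman screen matches hand rank computations", {
  pm <- rbind(c(10, 20, 30, 40),
              c(2, 1, 4, 3) * 10,
              c(5, 5, 5, 5))
  res <- spearmanScreen(pm, c(1, 2, 3, 4))
  expect_equal(res$rho[1], 1)
  expect_equal(res$rho[2], 0.6)     # hand rank computation
  expect_true(res$flagged[3])
  # negating the covariate negates every rho
  resNeg <- spearmanScreen(pm, -c(1, 2, 3, 4))
  expect_equal(resNeg$rho[1:2], -res$rho[1:2])
  # agrees with cor(method = "spearman") on random data
  set.seed(12)
  pm2 <- matrix(runif(120), 10, 12)
  cv <- runif(12)
  res2 <- spearmanScreen(pm2, cv)
  ref <- apply(pm2, 1, function(v) cor(v, cv, method = "spearman"))
  expect_equal(res2$rho, unname(ref), tolerance = 1e-12)
})

test_that("the Mann-Whitney comparison matches exact enumeration", {
  a <- c(0.9, 0.8); b <- c(0.1, 0.2)
  res <- compareAbsRho(a, b)
  expect_equal(res$U, 4)            # maximal
  expect_equal(res$p, oracleMannWhitney(a, b))
  # identical samples: central U, p near 1
  res2 <- compareAbsRho(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7))
  expect_equal(res2$U, 4.5)
  expect_gt(res2$p, 0.9)
  # invariance under a common monotone transform
  set.seed(2)
  x <- runif(12); y <- runif(15)
  expect_equal(compareAbsRho(x, y)$p,
               compareAbsRho(sqrt(x), sqrt(y))$p)
})
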