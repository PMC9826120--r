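# Independent oracles used to freeze expected values. Each is written
# from the definition, deliberately avoiding the implementation path it
# checks (brute force, enumeration, closed form).

# two-group binomial logit model fitted by direct numerical likelihood
# maximisation; returns LRT, dispersion from Pearson residuals, and the
# p-value under the same corrected-F convention as the package
oracleDmTest <- function(m, n, grp) {
  keep <- n > 0
  m <- m[keep]; n <- n[keep]; grp <- grp[keep]
  nll <- function(b) {
    p <- plogis(b[1] + b[2] * grp)
    -sum(dbinom(m, n, p, log = TRUE))
  }
  nll0 <- function(b0) {
    p <- plogis(b0)
    -sum(dbinom(m, n, p, log = TRUE))
  }
  full <- optim(c(0, 0), nll, method = "BFGS",
                control = list(reltol = 1e-14, maxit = 2000))
  full <- optim(full$par, nll, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 5000))
  null <- optimize(nll0, c(-30, 30), tol = 1e-10)
  lrt <- max(2 * (null$objective - full$value), 0)
  pfit <- plogis(full$par[1] + full$par[2] * grp)
  r2 <- (m - n * pfit)^2 / (n * pfit * (1 - pfit))
  r2[!is.finite(r2)] <- 0
  J <- length(m)
  phi <- if (J > 2) sum(r2) / (J - 2) else 1
  stat <- lrt / max(phi, 1)
  list(lrt = lrt, phi = phi,
       p = pf(stat, 1, max(J - 2, 1), lower.tail = FALSE))
}

# per-position CpG-island oracle: for every position, loop over all
# windows covering it and evaluate both thresholds directly
oracleCgi <- function(seq, window = 100, minlen = 200, minOE = 0.6,
                      minGC = 50) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  windowPasses <- function(i) {
    w <- ch[i:(i + window - 1)]
    nC <- sum(w == "C"); nG <- sum(w == "G")
    nCG <- sum(w[-window] == "C" & w[-1] == "G")
    gc <- 100 * (nC + nG) / window
    oe <- if (nC * nG > 0) (nCG * window) / (nC * nG) else 0
    gc >= minGC && oe >= minOE
  }
  passes <- vapply(seq_len(max(L - window + 1, 0)), windowPasses,
                   logical(1))
  cand <- logical(L)
  for (i in which(passes)) cand[i:(i + window - 1)] <- TRUE
  r <- rle(cand)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= minlen
  cbind(start = begs[keep], end = ends[keep])
}

# two-sided Fisher p by explicit hypergeometric enumeration from
# factorials (no call to fisher.test / dhyper)
oracleFisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  lp <- function(x) lchoose(r1, x) + lchoose(n - r1, c1 - x) -
    lchoose(n, c1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- exp(lp(xs))
  pObs <- exp(lp(a))
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# PWM score threshold by exhaustive enumeration of all 4^w sequences,
# on the same discretised score grid as the DP
oracleThreshold <- function(pwm, pValue, step = 0.01) {
  w <- pwm$width
  iscore <- round(pwm$log_odds / step)
  grids <- rep(list(1:4), w)
  seqs <- as.matrix(expand.grid(grids))
  scores <- numeric(nrow(seqs))
  probs <- numeric(nrow(seqs))
  for (k in seq_len(nrow(seqs))) {
    scores[k] <- sum(iscore[cbind(seqs[k, ], seq_len(w))]) * step
    probs[k] <- prod(pwm$background[seqs[k, ]])
  }
  # aggregate tied scores before taking the tail
  agg <- tapply(probs, round(scores / step), sum)
  sc <- as.numeric(names(agg)) * step
  ord <- order(sc)
  sc <- sc[ord]; pr <- as.numeric(agg)[ord]
  tailp <- rev(cumsum(rev(pr)))
  idx <- which(tailp <= pValue)
  if (length(idx)) sc[min(idx)] else sc[length(sc)]
}

# exact two-sided Mann-Whitney p by enumerating all label assignments
oracleMannWhitney <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  combs <- combn(length(pooled), nA)
  uOf <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(combs, 2, uOf)
  uObs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- nA * (length(pooled) - nA) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# ordinary least squares through the normal equations
oracleOLS <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# small helper: a MethylomeSE from explicit matrices
makeSE <- function(meth, cov, sex = NULL, temperature = NULL,
                   clutch = NULL) {
  n <- nrow(meth); J <- ncol(meth)
  loci <- data.frame(scaffold = "scafT", pos = seq_len(n) * 10L)
  sd <- data.frame(
    sample_id = sprintf("S%02d", seq_len(J)),
    tissue = "blood",
    sex = if (is.null(sex)) rep("F", J) else sex,
    temperature = if (is.null(temperature)) rep(30, J) else temperature,
    clutch = if (is.null(clutch)) rep("c1", J) else clutch)
  colnames(meth) <- colnames(cov) <- sd$sample_id
  MethylomeSE(loci, meth, cov, sampleData = sd)
}
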