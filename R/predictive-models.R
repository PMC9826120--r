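#' Train/test split of the study design
#'
#' `one_per_cell` draws exactly one randomly selected test sample from
#' each temperature-sex combination (the study design: 20 training and
#' 4 test samples from 24); `half_half` splits each cell as evenly as
#' possible into two halves (12/12 on the study design). Deterministic
#' given the seed.
#'
#' @param metadata sample metadata (data.frame with `sample_id`,
#'   `temperature`, `sex`).
#' @param scheme `"one_per_cell"` or `"half_half"`.
#' @param seed integer seed.
#' @return list with `train`, `test` (sample ids), `scheme`, `seed`.
#' @export
makeSplit <- function(metadata, scheme = c("one_per_cell", "half_half"),
                      seed = 1L) {
  scheme <- match.arg(scheme)
  cell <- paste(metadata$temperature, metadata$sex, sep = "_")
  ids <- split(metadata$sample_id, cell)
  if (any(lengths(ids) == 0L)) stop("empty temperature-sex cell")
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  test <- withr_seed(
    if (scheme == "one_per_cell")
      unlist(lapply(ids, function(v) sample(v, 1L)), use.names = FALSE)
    else
      unlist(lapply(ids, function(v) sample(v, floor(length(v) / 2))),
             use.names = FALSE))
  list(train = setdiff(metadata$sample_id, test), test = test,
       scheme = scheme, seed = as.integer(seed))
}

#' Candidate loci for the sparse predictor
#'
#' Loci differentially methylated for the target *within the training
#' set* at a stringent FDR (default 5%) *and* classified as DMCs of the
#' target class on the full data set: the intersection enters variable
#' selection.
#'
#' @param trainContrasts [runContrasts()] output computed on training
#'   samples only.
#' @param fullLabels [classifyDMCs()] output for the full data set.
#' @param target `"sex"` or `"temperature"`.
#' @param fdrTrain training-set FDR threshold (default 0.05).
#' @return character vector of locus keys ("scaffold:pos").
#' @export
selectCandidates <- function(trainContrasts, fullLabels,
                             target = c("sex", "temperature"),
                             fdrTrain = 0.05) {
  target <- match.arg(target)
  keyOf <- function(df) paste0(df$scaffold, ":", df$pos)
  sigIn <- function(nm) {
    df <- trainContrasts[[nm]]
    keyOf(df)[!is.na(df$q) & df$q < fdrTrain]
  }
  trainKeys <- if (target == "sex")
    union(sigIn("FvM"), sigIn("F34.5vM34.5"))
  else
    Reduce(union, lapply(c("30v33.5", "30v34.5", "33.5v34.5"), sigIn))
  fullKeys <- paste0(fullLabels$scaffold, ":", fullLabels$pos)
  fullTarget <- if (target == "sex")
    fullKeys[fullLabels$class %in% c("universal_sex", "sex")]
  else fullKeys[fullLabels$class == "temperature"]
  out <- intersect(trainKeys, fullTarget)
  if (!length(out))
    stop("empty candidate set; effects too weak for selection at FDR ",
         fdrTrain)
  out
}

#' Fit a sparse elastic-net predictor
#'
#' Penalized regression (glmnet) over percent methylation at candidate
#' loci: binomial logistic for sex, gaussian for incubation
#' temperature, elastic-net mixing `alpha` (default 0.5). The penalty
#' `lambda` minimising the cross-validated mean error (squared error on
#' probabilities by default, matching the selection rule used
#' throughout; deviance available via `cvMeasure`) over `folds`
#' seeded, class-stratified folds is selected, and loci with zero
#' coefficients are dropped. Features are standardised internally;
#' coefficients are reported on the percent-methylation scale.
#'
#' @param X complete (imputed) percent matrix, samples x loci, with
#'   locus keys as column names.
#' @param y factor (binomial) or numeric (gaussian) response.
#' @param family `"binomial"` or `"gaussian"`.
#' @param alpha mixing parameter (default 0.5).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param cvMeasure `"mse"` (default) or `"deviance"` (binomial only).
#' @param lambda optional fixed penalty: skips cross-validation and
#'   fits at exactly this value (0 gives the unpenalised fit).
#' @return a [SparsePredictor-class].
#' @export
fitElasticNet <- function(X, y, family = c("binomial", "gaussian"),
                          alpha = 0.5, folds = 5L, seed = 1L,
                          cvMeasure = c("mse", "deviance"),
                          lambda = NULL) {
  family <- match.arg(family)
  cvMeasure <- match.arg(cvMeasure)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete; impute first")
  if (nrow(X) < folds) stop("need at least as many samples as folds")
  classes <- character()
  if (family == "binomial") {
    y <- factor(y)
    if (nlevels(y) != 2L) stop("binomial response must have 2 levels")
    classes <- levels(y)
  }
  if (!is.null(lambda)) {
    # descending path ending at the requested value for stable warm starts
    path <- sort(unique(c(exp(seq(log(100), log(max(lambda, 1e-4)),
                                  length.out = 30)), lambda)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = family, alpha = alpha,
                          lambda = path, standardize = TRUE,
                          thresh = 1e-14)
    beta <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE,
                                   x = X, y = y))
    sel <- lambda
    cvErr <- NA_real_
  } else {
    set.seed(seed)
    foldid <- integer(nrow(X))
    strat <- if (family == "binomial") y else factor(rep("all", nrow(X)))
    for (lv in levels(strat)) {
      idx <- which(strat == lv)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    cv <- glmnet::cv.glmnet(X, y, family = family, alpha = alpha,
                            foldid = foldid,
                            type.measure = if (family == "binomial")
                              cvMeasure else "mse",
                            standardize = TRUE)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
    sel <- cv$lambda.min
    cvErr <- cv$cvm[which.min(abs(cv$lambda - cv$lambda.min))]
  }
  keep <- which(beta[-1L] != 0)
  new("SparsePredictor", family = family, alpha = alpha,
      lambda = sel,
      loci = colnames(X)[keep], coefficients = beta[-1L][keep],
      intercept = beta[1L], classes = classes,
      cvError = cvErr, seed = as.integer(seed))
}

#' Predict from a sparse methylation model
#'
#' @param model a [SparsePredictor-class].
#' @param X percent matrix, samples x loci, containing every model
#'   locus as a column (error listing missing loci otherwise).
#' @return binomial: probability of the second class, in [0, 1];
#'   gaussian: predicted temperature in degrees C (unclamped).
#' @export
predictSparse <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model@loci, colnames(X))
  if (length(missing))
    stop("model loci absent from X: ", paste(missing, collapse = ", "))
  eta <- drop(X[, model@loci, drop = FALSE] %*% model@coefficients) +
    model@intercept
  if (model@family == "binomial") stats::plogis(eta) else eta
}

#' Evaluate predictions against truth
#'
#' Binomial: accuracy at the 0.5 cutoff plus per-class mean and
#' standard error of the predicted probabilities. Gaussian: coefficient
#' of determination `R2 = 1 - SS_res / SS_tot` of actual vs predicted,
#' and mean absolute error.
#'
#' @param predictions numeric predictions from [predictSparse()].
#' @param truth factor (binomial) or numeric (gaussian) truth.
#' @param family `"binomial"` or `"gaussian"`.
#' @return named list of metrics.
#' @export
evaluatePredictions <- function(predictions,
                                truth,
                                family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  if (family == "binomial") {
    truth <- factor(truth)
    predClass <- levels(truth)[(predictions > 0.5) + 1L]
    byClass <- lapply(split(predictions, truth), function(v)
      c(mean = mean(v), se = stats::sd(v) / sqrt(length(v))))
    list(accuracy = mean(predClass == as.character(truth)),
         byClass = byClass)
  } else {
    res <- truth - predictions
    sstot <- sum((truth - mean(truth))^2)
    list(r2 = 1 - sum(res^2) / sstot, mae = mean(abs(res)))
  }
}
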