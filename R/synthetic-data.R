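#' The default incubation study design
#'
#' One row per hatchling: eight females at 30 C, eight males at 33.5 C,
#' and four of each sex at 34.5 C, drawn from five clutches with
#' balanced representation across temperature-sex cells.
#'
#' @return data.frame with `sample_id`, `tissue`, `sex`, `temperature`,
#'   `clutch`, `role`.
#' @export
defaultDesign <- function() {
  clutches <- c("AP-03", "AP-04", "AP-05", "AP-06", "AP-08")
  cell <- function(temp, sex, perClutch) {
    cl <- rep(clutches, perClutch)
    data.frame(sex = sex, temperature = temp, clutch = cl)
  }
  d <- rbind(cell(30, "F", c(2L, 2L, 1L, 1L, 2L)),
             cell(33.5, "M", c(2L, 2L, 1L, 1L, 2L)),
             cell(34.5, "F", c(2L, 1L, 0L, 1L, 0L)),
             cell(34.5, "M", c(2L, 1L, 0L, 1L, 0L)))
  d <- cbind(sample_id = sprintf("B%02d", seq_len(nrow(d))),
             tissue = "blood", d, role = "unassigned")
  d
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: the 4-temperature x 2-sex x
#' 5-clutch blood design (24 samples), ~30x negative-binomial read
#' coverage, a bimodal baseline methylome (three-component mixture:
#' Beta(0.5, 10) hypomethylated, Uniform(0.2, 0.8) intermediate,
#' Beta(10, 0.5) hypermethylated), beta-binomial methylated counts with
#' intra-locus correlation `betaBinomialRho`, clutch-level random
#' intercepts on the logit scale, and planted sex and temperature
#' effects. Sex effects are planted as shifts from a hypermethylated
#' baseline toward intermediate methylation in one sex (the observed
#' pattern for sex-associated loci); a fraction of them are expressed
#' only at 34.5 C, reproducing the high-temperature-specific sex DMCs.
#' Hormone levels are lognormal with a subtle (near-threshold) sex
#' offset for oestradiol.
#'
#' @param seed integer seed.
#' @param nScaffolds,scaffoldLength synthetic genome shape.
#' @param nGenes,cgiFraction,nMotifs gene, CpG-island-tract and motif
#'   planting parameters for [simulateGenome()].
#' @param nLoci number of CpG loci carried into the count simulation.
#' @param design design data.frame (default [defaultDesign()]).
#' @param coverageMean,coverageSize negative-binomial coverage mean and
#'   size (dispersion) per cell.
#' @param baselineWeights mixture weights (hypo, intermediate, hyper).
#' @param betaBinomialRho intra-locus correlation in [0, 1).
#' @param fracSexDmc,fracTempDmc planted fractions of responsive loci.
#' @param sexEffectLogit planted sex effect (logit shift toward
#'   intermediate methylation in the affected sex).
#' @param frac345Specific fraction of sex loci whose effect is
#'   expressed only at 34.5 C.
#' @param tempSlopeLogitPerC planted temperature slope (logit per C).
#' @param clutchSdLogit SD of clutch random intercepts (logit).
#' @param hormoneMeanlog named list with per-sex lognormal meanlog for
#'   `e2` and `testosterone`; `hormoneSdlog` the common sdlog.
#' @return a list with class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nScaffolds = 3L,
                             scaffoldLength = 20000L, nGenes = 6L,
                             cgiFraction = 0.05, nMotifs = 4L,
                             nLoci = 2000L, design = defaultDesign(),
                             coverageMean = 30, coverageSize = 8,
                             baselineWeights = c(hypo = 0.25, mid = 0.25,
                                                 hyper = 0.5),
                             betaBinomialRho = 0.05,
                             fracSexDmc = 0.01, fracTempDmc = 0.01,
                             sexEffectLogit = 2.5, frac345Specific = 0.3,
                             tempSlopeLogitPerC = 0.6,
                             clutchSdLogit = 0.3,
                             hormoneMeanlog = list(
                               e2 = c(F = 3.4, M = 3.2),
                               testosterone = c(F = 3.0, M = 3.0)),
                             hormoneSdlog = 0.5) {
  stopifnot(fracSexDmc >= 0, fracTempDmc >= 0,
            fracSexDmc + fracTempDmc <= 1,
            betaBinomialRho >= 0, betaBinomialRho < 1,
            all(baselineWeights >= 0))
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a genome with CpG-island tracts, genes and planted motifs
#'
#' Scaffolds have a CG-depleted vertebrate-like background; a
#' `cgiFraction` of each scaffold is covered by CG-rich tracts
#' (recorded as island truth); non-overlapping genes with exons are
#' placed along the scaffolds; and consensus oestrogen- and
#' androgen-response-element sequences are planted at recorded
#' positions. Deterministic given `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` (`DNAStringSet`), `genes` (gene table as
#'   accepted by [geneModels()]), `cgiTruth` (`GRanges`), `motifs`
#'   (data.frame with planted positions and the planted sequence).
#' @export
simulateGenome <- function(config) {
  set.seed(config$seed)
  L <- config$scaffoldLength
  bases <- c("A", "C", "G", "T")
  scafNames <- sprintf("scaf%d", seq_len(config$nScaffolds))
  # consensus-like ERE (inverted repeat) and ARE sequences
  consensus <- c(ERE = "AGGTCACAGTGACCT", ARE = "AGAACAGCAAGTGCT")
  genomeChars <- list(); cgiRanges <- list(); motifRows <- list()
  for (si in seq_along(scafNames)) {
    ch <- sample(bases, L, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))
    # deplete background CG dinucleotides to vertebrate-like levels
    cgAt <- which(ch[-L] == "C" & ch[-1L] == "G")
    flip <- cgAt[stats::runif(length(cgAt)) < 0.75]
    ch[flip + 1L] <- sample(c("A", "T"), length(flip), replace = TRUE)
    # CG-rich island tracts
    nTract <- max(0L, round(config$cgiFraction * L / 400))
    tractStarts <- if (nTract > 0)
      sort(sample(seq(200L, L - 600L, by = 50L), nTract)) else integer()
    if (length(tractStarts) > 1L)
      tractStarts <- tractStarts[c(TRUE, diff(tractStarts) > 1200)]
    for (ts in tractStarts) {
      tract <- rep(c("C", "G"), 200)
      mut <- stats::runif(400) < 0.15
      tract[mut] <- sample(bases, sum(mut), replace = TRUE)
      ch[ts:(ts + 399L)] <- tract
    }
    if (length(tractStarts))
      cgiRanges[[si]] <- GRanges(factor(rep(scafNames[si],
                                            length(tractStarts)),
                                        levels = scafNames),
                                 IRanges(tractStarts, tractStarts + 399L))
    # plant motif consensus sequences outside island tracts
    if (config$nMotifs > 0) {
      cand <- seq(500L, L - 500L, by = 997L)
      if (length(tractStarts))
        cand <- cand[!vapply(cand, function(p)
          any(p >= tractStarts - 420 & p <= tractStarts + 420), logical(1))]
      pos <- sample(cand, min(config$nMotifs, length(cand)))
      for (k in seq_along(pos)) {
        mt <- names(consensus)[1L + (k %% 2L)]
        sq <- strsplit(consensus[[mt]], "")[[1L]]
        ch[pos[k]:(pos[k] + length(sq) - 1L)] <- sq
        motifRows[[length(motifRows) + 1L]] <-
          data.frame(scaffold = scafNames[si], pos = pos[k] - 1L,
                     motif = mt, sequence = consensus[[mt]])
      }
    }
    genomeChars[[si]] <- paste(ch, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(genomeChars))
  names(genome) <- scafNames
  # non-overlapping genes with exon structure
  genes <- NULL
  if (config$nGenes > 0) {
    perScaf <- rep(seq_along(scafNames),
                   length.out = config$nGenes)
    rows <- lapply(seq_len(config$nGenes), function(gi) {
      sc <- perScaf[gi]
      slotW <- floor(L / sum(perScaf == sc))
      slot <- sum(perScaf[seq_len(gi)] == sc) - 1L
      gs <- slot * slotW + 1500L
      glen <- min(3000L, slotW - 3000L)
      if (glen < 300L) stop("infeasible gene layout: too many genes ",
                            "for the scaffold length")
      ge <- gs + glen
      nEx <- sample(2:4, 1L)
      bnd <- sort(sample(seq(gs + 50L, ge - 50L, by = 10L), 2L * nEx - 2L))
      es <- c(gs, bnd[seq(2, length(bnd), by = 2)])
      ee <- c(bnd[seq(1, length(bnd), by = 2)], ge)
      data.frame(gene_id = sprintf("gene%02d", gi),
                 scaffold = scafNames[sc],
                 strand = sample(c("+", "-"), 1L),
                 tx_start = gs, tx_end = ge,
                 exon_starts = paste(es, collapse = ","),
                 exon_ends = paste(ee, collapse = ","))
    })
    genes <- do.call(rbind, rows)
  }
  cgiTruth <- if (length(cgiRanges)) do.call(c, cgiRanges) else GRanges()
  GenomeInfoDb::seqlevels(cgiTruth) <- scafNames
  GenomeInfoDb::seqlengths(cgiTruth) <- stats::setNames(rep(L,
    length(scafNames)), scafNames)
  list(genome = genome, genes = genes, cgiTruth = cgiTruth,
       motifs = if (length(motifRows)) do.call(rbind, motifRows) else
         data.frame(scaffold = character(), pos = integer(),
                    motif = character(), sequence = character()))
}

.rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

#' Simulate RRBS methylation counts for the study design
#'
#' Per-locus baseline methylation is drawn from the bimodal mixture;
#' planted sex loci start from a hypermethylated baseline and shift by
#' `-sexEffectLogit` toward intermediate methylation in one randomly
#' chosen sex (a `frac345Specific` subset only in 34.5 C hatchlings);
#' planted temperature loci change linearly on the logit scale with
#' centered temperature. Sample-level clutch intercepts are normal on
#' the logit scale. Coverage is negative-binomial (zero coverage gives
#' a missing cell) and methylated counts are beta-binomial.
#'
#' Model per locus i and sample j:
#' `logit(pi_ij) = logit(pi_i) + effects_ij + clutch_j`,
#' `n_ij ~ NegBin(coverageMean, coverageSize)`,
#' `m_ij ~ BetaBinomial(n_ij, pi_ij, rho)`.
#'
#' @param config a [simulationConfig()].
#' @param genome optional genome from [simulateGenome()]; when given,
#'   loci are placed on its actual CpG positions, otherwise at evenly
#'   spaced synthetic positions.
#' @param dir optional directory: per-sample bismark-style coverage
#'   files and a metadata TSV are written there.
#' @param splitStrands when writing coverage files, divide each CpG's
#'   reads binomially between the plus-strand C and the minus-strand G
#'   at position + 1, exercising strand merging downstream.
#' @return list with `se` (a [MethylomeSE]), `metadata`, `truth`
#'   (per-locus class, affected sex / slope, baseline), `clutchEffects`,
#'   and `files` when `dir` was given.
#' @export
simulateMethylomes <- function(config, genome = NULL, dir = NULL,
                               splitStrands = FALSE) {
  set.seed(config$seed + 1L)
  md <- validateSampleMetadata(config$design)
  n <- config$nLoci
  J <- nrow(md)
  # locus placement
  if (!is.null(genome)) {
    idx <- cpgIndex(genome$genome)
    all <- do.call(rbind, lapply(names(idx), function(sc)
      data.frame(scaffold = sc, pos = idx[[sc]])))
    if (nrow(all) < n) stop("genome has fewer CpGs than nLoci")
    pick <- sort(sample.int(nrow(all), n))
    loci <- all[pick, ]
  } else {
    per <- ceiling(n / config$nScaffolds)
    loci <- do.call(rbind, lapply(seq_len(config$nScaffolds), function(si)
      data.frame(scaffold = sprintf("scaf%d", si),
                 pos = seq(100L, by = 10L, length.out = per))))[seq_len(n), ]
  }
  rownames(loci) <- NULL
  # baseline methylation mixture
  w <- config$baselineWeights / sum(config$baselineWeights)
  comp <- sample.int(3L, n, replace = TRUE, prob = w)
  pi0 <- numeric(n)
  pi0[comp == 1L] <- stats::rbeta(sum(comp == 1L), 0.5, 10)
  pi0[comp == 2L] <- stats::runif(sum(comp == 2L), 0.2, 0.8)
  pi0[comp == 3L] <- stats::rbeta(sum(comp == 3L), 10, 0.5)
  # planted classes
  nSex <- round(config$fracSexDmc * n)
  nTemp <- round(config$fracTempDmc * n)
  cls <- rep("null", n)
  planted <- sample.int(n, nSex + nTemp)
  sexLoci <- planted[seq_len(nSex)]
  tempLoci <- setdiff(planted, sexLoci)
  cls[sexLoci] <- "sex"; cls[tempLoci] <- "temperature"
  # sex loci: hypermethylated baseline, shifted toward intermediate
  pi0[sexLoci] <- stats::runif(nSex, 0.8, 0.95)
  affectedSex <- sample(c("F", "M"), n, replace = TRUE)
  only345 <- rep(FALSE, n)
  if (nSex > 0)
    only345[sexLoci] <- stats::runif(nSex) < config$frac345Specific
  slope <- numeric(n)
  if (nTemp > 0)
    slope[tempLoci] <- sample(c(-1, 1), nTemp, replace = TRUE) *
      config$tempSlopeLogitPerC
  clutches <- sort(unique(md$clutch))
  clutchEff <- stats::setNames(stats::rnorm(length(clutches), 0,
                                            config$clutchSdLogit), clutches)
  tbar <- mean(md$temperature)
  eps <- 1e-4
  logit <- function(p) log(p / (1 - p))
  base <- logit(pmin(pmax(pi0, eps), 1 - eps))
  meth <- matrix(NA_integer_, n, J)
  cov <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    eta <- base + slope * (md$temperature[j] - tbar) + clutchEff[md$clutch[j]]
    sexHit <- cls == "sex" & md$sex[j] == affectedSex &
      (!only345 | md$temperature[j] == 34.5)
    eta[sexHit] <- eta[sexHit] - config$sexEffectLogit
    p <- stats::plogis(eta)
    nn <- stats::rnbinom(n, size = config$coverageSize,
                         mu = config$coverageMean)
    mm <- .rbetabinom(n, nn, p, config$betaBinomialRho)
    obs <- nn > 0L
    meth[obs, j] <- mm[obs]
    cov[obs, j] <- nn[obs]
  }
  colnames(meth) <- colnames(cov) <- md$sample_id
  se <- MethylomeSE(loci, meth, cov, sampleData = md)
  truth <- data.frame(loci, class = cls,
                      affected_sex = ifelse(cls == "sex", affectedSex, NA),
                      only_34_5 = ifelse(cls == "sex", only345, NA),
                      temp_slope = slope, baseline = pi0)
  out <- list(se = se, metadata = md, truth = truth,
              clutchEffects = clutchEff)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character()
    for (j in seq_len(J)) {
      obs <- which(!is.na(cov[, j]))
      calls <- data.frame(scaffold = loci$scaffold[obs],
                          pos = loci$pos[obs],
                          meth = meth[obs, j],
                          unmeth = cov[obs, j] - meth[obs, j],
                          coverage = cov[obs, j])
      if (splitStrands) {
        mPlus <- stats::rbinom(nrow(calls), calls$meth, 0.5)
        uPlus <- stats::rbinom(nrow(calls), calls$unmeth, 0.5)
        plus <- data.frame(scaffold = calls$scaffold, pos = calls$pos,
                           meth = mPlus, unmeth = uPlus,
                           coverage = mPlus + uPlus)
        minus <- data.frame(scaffold = calls$scaffold, pos = calls$pos + 1L,
                            meth = calls$meth - mPlus,
                            unmeth = calls$unmeth - uPlus,
                            coverage = calls$coverage - mPlus - uPlus)
        calls <- rbind(plus, minus)
        calls <- calls[calls$coverage > 0L, ]
        calls <- calls[order(calls$scaffold, calls$pos), ]
      }
      f <- file.path(dir, paste0(md$sample_id[j], ".cov"))
      writeBismarkCoverage(calls, f)
      files <- c(files, f)
    }
    utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$files <- files
  }
  out
}

#' Simulate plasma hormone concentrations
#'
#' Lognormal per-sample oestradiol and testosterone with a per-sex
#' meanlog offset (default: a subtle, near-threshold oestradiol
#' difference and none for testosterone). Seeded by `config$seed`.
#'
#' @param metadata sample metadata data.frame.
#' @param config a [simulationConfig()].
#' @return `metadata` with `e2` and `testosterone` columns appended.
#' @export
simulateHormones <- function(metadata, config) {
  set.seed(config$seed + 2L)
  sex <- ifelse(metadata$sex %in% c("F", "M"), metadata$sex, "F")
  metadata$e2 <- stats::rlnorm(nrow(metadata),
                               config$hormoneMeanlog$e2[sex],
                               config$hormoneSdlog)
  metadata$testosterone <- stats::rlnorm(
    nrow(metadata), config$hormoneMeanlog$testosterone[sex],
    config$hormoneSdlog)
  metadata
}
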