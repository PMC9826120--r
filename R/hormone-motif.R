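#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR text format:
#' ```
#' >MA0112.3 ESR1
#' A [ 123  45 ... ]
#' C [ ... ]
#' G [ ... ]
#' T [ ... ]
#' ```
#' (brackets optional). Returns the raw count matrix; conversion to a
#' scoring matrix happens in [pwmFromCounts()].
#'
#' @param path path to the PFM file (first motif read if several).
#' @return list with `motif_id`, `name`, `counts` (4 x width matrix,
#'   rows A, C, G, T).
#' @export
readJasparPfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR header line ('>...') found")
  h <- strsplit(sub("^>", "", lines[hdr[1L]]), "\\s+")[[1L]]
  body <- lines[(hdr[1L] + 1L):(if (length(hdr) > 1L) hdr[2L] - 1L
                                else length(lines))]
  rows <- lapply(c("A", "C", "G", "T"), function(b) {
    ln <- body[grepl(paste0("^", b, "\\b"), body)]
    if (length(ln) != 1L) stop("missing or duplicated row for base ", b)
    as.numeric(strsplit(trimws(gsub("[][A-Za-z]", " ", ln)), "\\s+")[[1L]])
  })
  w <- unique(lengths(rows))
  if (length(w) != 1L) stop("unequal row lengths in PFM")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  list(motif_id = h[1L], name = if (length(h) > 1L) h[2L] else NA_character_,
       counts = counts)
}

#' Build a log-odds PWM from a count matrix
#'
#' Counts are converted to per-position probabilities with a total
#' pseudocount of `pseudocount` distributed by the background
#' frequencies, then to log2 odds against the background.
#'
#' @param counts 4 x width matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param background named numeric(4) of background base frequencies
#'   (default uniform); normalised internally.
#' @param pseudocount total pseudocount per position (default 0.8).
#' @param motif_id optional identifier carried through to hits.
#' @return object of class `PWM`: list with `motif_id`, `width`,
#'   `probs`, `background`, `log_odds` (4 x width, log2).
#' @export
pwmFromCounts <- function(counts, background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                          pseudocount = 0.8, motif_id = NA_character_) {
  stopifnot(nrow(counts) == 4L)
  rownames(counts) <- c("A", "C", "G", "T")
  background <- background[c("A", "C", "G", "T")] / sum(background)
  tot <- colSums(counts)
  probs <- sweep(counts, 2, tot, "/")
  probs <- sweep(probs * rep(tot, each = 4) + pseudocount * background,
                 2, tot + pseudocount, "/")
  lo <- log2(probs / background)
  structure(list(motif_id = motif_id, width = ncol(counts), probs = probs,
                 background = background, log_odds = lo), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$motif_id, "- width", x$width, "\n")
  invisible(x)
}

#' Score threshold for a target p-value by dynamic programming
#'
#' Computes the exact distribution of the PWM score of a random
#' background sequence by dynamic programming over scores discretised
#' to `step` (log2 units) and returns the smallest achievable score
#' `s` with `P(score >= s) <= pValue`.
#'
#' @param pwm a `PWM` from [pwmFromCounts()].
#' @param pValue target p-value in (0, 1) (default 2e-6).
#' @param step score discretisation (default 0.01).
#' @return list with `threshold` (score, log2 units), `pAttained`
#'   (tail probability at the threshold), `degenerate` (TRUE when all
#'   sequences score equally).
#' @export
pwmThreshold <- function(pwm, pValue = 2e-6, step = 0.01) {
  if (pValue <= 0 || pValue >= 1) stop("pValue must be in (0, 1)")
  iscore <- round(pwm$log_odds / step)
  offset <- apply(iscore, 2, min)
  dist <- 1
  base <- 0
  for (j in seq_len(pwm$width)) {
    sh <- iscore[, j] - offset[j]
    width <- max(sh)
    newdist <- numeric(length(dist) + width)
    for (b in 1:4)
      newdist[seq_along(dist) + sh[b]] <-
        newdist[seq_along(dist) + sh[b]] + dist * pwm$background[b]
    dist <- newdist
    base <- base + offset[j]
  }
  scores <- (base + seq_along(dist) - 1L) * step
  tail <- rev(cumsum(rev(dist)))
  # restrict to achievable scores (positive-probability support)
  support <- dist > 0
  scores <- scores[support]
  tail <- tail[support]
  if (length(scores) == 1L)
    return(list(threshold = scores[1L], pAttained = 1, degenerate = TRUE))
  idx <- which(tail <= pValue)
  if (!length(idx)) {
    # even the maximal score is more probable than pValue
    threshold <- scores[length(scores)]
    pAtt <- tail[length(tail)]
  } else {
    threshold <- scores[min(idx)]
    pAtt <- tail[min(idx)]
  }
  list(threshold = threshold, pAttained = pAtt, degenerate = FALSE)
}

.DNA_CODES <- stats::setNames(1:4, c("A", "C", "G", "T"))

.encodeSeq <- function(s) {
  ch <- strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1L]]
  unname(.DNA_CODES[ch])     # NA for N and other ambiguity codes
}

.scanStrand <- function(code, lo, threshold) {
  w <- ncol(lo)
  L <- length(code)
  if (L < w) return(data.frame(start = integer(), score = numeric()))
  n <- L - w + 1L
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(w)) {
    cj <- code[j:(j + n - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    sc <- sc + lo[cj, j]
  }
  hit <- ok & sc >= threshold
  data.frame(start = which(hit), score = sc[hit])
}

#' Scan a genome with a PWM on both strands
#'
#' Windows containing N are skipped; minus-strand matches are reported
#' at their plus-strand coordinates (the window's leftmost base).
#' Scores are evaluated on the same discretised grid (`step`) as the
#' threshold distribution of [pwmThreshold()], so the attained tail
#' probability describes the scan exactly.
#'
#' @param genome `DNAStringSet` (or FASTA path).
#' @param pwm a `PWM`.
#' @param threshold score threshold, typically
#'   `pwmThreshold(pwm, p)$threshold`.
#' @param step score discretisation, matching [pwmThreshold()]
#'   (default 0.01).
#' @return `GRanges` of hits with `score` and `strand` set.
#' @export
scanPwm <- function(genome, pwm, threshold, step = 0.01) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  lo <- round(pwm$log_odds / step) * step
  threshold <- threshold - step / 1e6      # guard float comparison
  # reverse-complement scoring matrix: scanning the plus strand with it
  # equals scanning the minus strand with the original
  loRC <- lo[4:1, ncol(lo):1, drop = FALSE]
  rownames(loRC) <- rownames(lo)
  res <- lapply(names(genome), function(sc) {
    code <- .encodeSeq(genome[[sc]])
    plus <- .scanStrand(code, lo, threshold)
    minus <- .scanStrand(code, loRC, threshold)
    gr <- GRanges(factor(rep(sc, nrow(plus) + nrow(minus)),
                         levels = names(genome)),
                  IRanges(c(plus$start, minus$start), width = pwm$width),
                  strand = rep(c("+", "-"), c(nrow(plus), nrow(minus))))
    gr$score <- c(plus$score, minus$score)
    gr
  })
  out <- do.call(c, res)
  GenomeInfoDb::seqlevels(out) <- names(genome)
  GenomeInfoDb::seqlengths(out) <-
    stats::setNames(Biostrings::width(genome), names(genome))
  sort(out, ignore.strand = TRUE)
}

#' Proportion of loci within distance cutoffs of motif hits
#'
#' Distance is the minimal bp gap between a locus and any hit (0 when
#' overlapping); loci on scaffolds without hits count as beyond every
#' cutoff. When a background locus set is supplied, a per-cutoff
#' two-sided Fisher test (within/beyond x set) with BH adjustment is
#' added, via the same machinery as [enrichmentTest()].
#'
#' @param loci `GRanges` (or [MethylomeSE]) of query loci (e.g. DMCs).
#' @param hits `GRanges` of motif hits from [scanPwm()].
#' @param cutoffs distances in bp (default 1000, 2500, 5000).
#' @param background optional `GRanges` of comparison loci (e.g. all
#'   covered CpGs, excluding the queries).
#' @return list with `distance` (per-locus), `proportions` (per
#'   cutoff), and, with a background, `tests` (data.frame per cutoff
#'   with `odds_ratio`, `p`, `q`).
#' @export
motifProximity <- function(loci, hits, cutoffs = c(1000, 2500, 5000),
                           background = NULL) {
  distTo <- function(q) {
    d <- rep(Inf, length(q))
    hh <- GenomicRanges::distanceToNearest(q, hits, ignore.strand = TRUE)
    d[S4Vectors::queryHits(hh)] <- S4Vectors::mcols(hh)$distance
    d
  }
  if (is(loci, "MethylomeSE")) loci <- granges(loci)
  d <- distTo(loci)
  props <- vapply(cutoffs, function(ct) mean(d <= ct), numeric(1))
  names(props) <- paste0("within_", cutoffs)
  out <- list(distance = d, proportions = props)
  if (!is.null(background)) {
    if (is(background, "MethylomeSE")) background <- granges(background)
    db <- distTo(background)
    tests <- do.call(rbind, lapply(cutoffs, function(ct) {
      et <- enrichmentTest(
        c(within = sum(d <= ct), beyond = sum(d > ct)),
        c(within = sum(db <= ct), beyond = sum(db > ct)))
      data.frame(cutoff = ct, odds_ratio = et$odds_ratio[1L],
                 p = et$p[1L])
    }))
    tests$q <- bhAdjust(tests$p)
    out$tests <- tests
  }
  out
}
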