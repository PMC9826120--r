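#' Read a bismark-style coverage file
#'
#' Parses the six-column tab-separated coverage format produced by
#' bismark's coverage2cytosine / methylation extractor:
#' `chrom  start  end  percent  count_methylated  count_unmethylated`
#' with 1-based inclusive coordinates. Positions are shifted to the
#' package's 0-based convention at this boundary. The percent column is
#' recomputed from the counts; a discrepancy larger than 0.5 percentage
#' points raises a warning (the call is kept, with the recomputed value).
#'
#' @param path path to the coverage file (plain text, optionally empty).
#' @return `data.frame` with columns `scaffold`, `pos` (0-based),
#'   `meth`, `unmeth`, `coverage`.
#' @export
readBismarkCoverage <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(scaffold = character(), pos = integer(),
                      meth = integer(), unmeth = integer(),
                      coverage = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed coverage line ", which(nf < 6L)[1L],
         ": expected >= 6 tab-separated columns")
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  scaffold <- getcol(1L)
  start <- suppressWarnings(as.integer(getcol(2L)))
  pct <- suppressWarnings(as.numeric(getcol(4L)))
  meth <- suppressWarnings(as.integer(getcol(5L)))
  unmeth <- suppressWarnings(as.integer(getcol(6L)))
  bad <- which(is.na(start) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop("malformed coverage line ", bad[1L], ": non-numeric field")
  if (any(meth < 0L | unmeth < 0L))
    stop("negative counts at line ", which(meth < 0L | unmeth < 0L)[1L])
  coverage <- meth + unmeth
  recomputed <- ifelse(coverage > 0L, 100 * meth / coverage, NA_real_)
  off <- !is.na(pct) & !is.na(recomputed) & abs(pct - recomputed) > 0.5
  if (any(off))
    warning(sum(off), " line(s) with percent column off by > 0.5 ",
            "percentage points from the counts; counts taken as truth")
  data.frame(scaffold = scaffold, pos = start - 1L,
             meth = meth, unmeth = unmeth, coverage = coverage)
}

#' Write calls in bismark coverage format
#'
#' Inverse of [readBismarkCoverage()]; used mainly by the simulator so
#' fixtures and real data flow through the same reader.
#'
#' @param calls data.frame as returned by [readBismarkCoverage()].
#' @param path output path.
#' @export
writeBismarkCoverage <- function(calls, path) {
  pct <- ifelse(calls$coverage > 0, 100 * calls$meth / calls$coverage, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   calls$scaffold, calls$pos + 1L, calls$pos + 1L,
                   format(pct, trim = TRUE), calls$meth, calls$unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Index plus-strand CpG positions of a genome
#'
#' @param genome `DNAStringSet` (or path to a FASTA file).
#' @return named list, one sorted integer vector of 0-based CpG (the C of
#'   "CG") positions per scaffold.
#' @export
cpgIndex <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  idx <- lapply(seq_along(genome), function(i)
    Biostrings::start(Biostrings::matchPattern("CG", genome[[i]])) - 1L)
  names(idx) <- names(genome)
  idx
}

#' Merge plus- and minus-strand calls of each CpG
#'
#' Reads covering the two strands of one CpG report at the plus-strand C
#' (position p) and at the G one base downstream (p + 1). This merges the
#' two into a single call at p, summing counts; total methylated and
#' total coverage are conserved. With a reference CpG index (see
#' [cpgIndex()]), calls are assigned exactly: a call at an indexed
#' position is plus-strand, a call one base after an indexed position is
#' its minus-strand mate, and anything else is dropped with a warning.
#' Without a reference, adjacent positions (p, p + 1) are paired
#' greedily left to right, which is exact for data from the simulator.
#'
#' @param calls data.frame of calls (one sample).
#' @param cpgIndex optional reference index from [cpgIndex()].
#' @return merged data.frame of calls, one row per CpG.
#' @export
mergeStrands <- function(calls, cpgIndex = NULL) {
  if (!nrow(calls)) return(calls)
  out <- lapply(split(calls, calls$scaffold), function(cc) {
    cc <- cc[order(cc$pos), , drop = FALSE]
    if (!is.null(cpgIndex)) {
      ref <- cpgIndex[[cc$scaffold[1L]]]
      isPlus <- cc$pos %in% ref
      isMinus <- !isPlus & (cc$pos - 1L) %in% ref
      orphan <- !isPlus & !isMinus
      if (any(orphan)) {
        warning(sum(orphan), " call(s) on ", cc$scaffold[1L],
                " match no reference CpG; dropped")
        cc <- cc[!orphan, , drop = FALSE]
        isPlus <- isPlus[!orphan]
      }
      anchor <- ifelse(isPlus, cc$pos, cc$pos - 1L)
    } else {
      # reference-free: pair (p, p+1) greedily from the left
      anchor <- cc$pos
      i <- 1L
      while (i < nrow(cc)) {
        if (anchor[i + 1L] == anchor[i] + 1L && anchor[i] == cc$pos[i]) {
          anchor[i + 1L] <- anchor[i]
          i <- i + 2L
        } else i <- i + 1L
      }
    }
    agg <- rowsum(cbind(meth = cc$meth, unmeth = cc$unmeth), anchor)
    data.frame(scaffold = cc$scaffold[1L],
               pos = as.integer(rownames(agg)),
               meth = as.integer(agg[, "meth"]),
               unmeth = as.integer(agg[, "unmeth"]),
               coverage = as.integer(agg[, "meth"] + agg[, "unmeth"]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read the sample metadata table
#'
#' Expects a tab-separated file with header columns `sample_id`,
#' `tissue` (blood/gonad), `sex` (F/M/unknown), `temperature` (degrees
#' C), `clutch`, and optionally `e2`, `testosterone`, `role`
#' (train/test/unassigned). Sex may be unknown only for gonad samples
#' (embryos sampled before phenotypic sex is observable).
#'
#' @param path path to the TSV.
#' @return `data.frame`, one row per sample, validated.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in intersect(c("e2", "testosterone"), colnames(md)))
    md[[col]] <- as.numeric(md[[col]])
  validateSampleMetadata(md)
}

#' @rdname readSampleMetadata
#' @param md a metadata `data.frame` to validate in place.
#' @export
validateSampleMetadata <- function(md) {
  req <- c("sample_id", "tissue", "sex", "temperature", "clutch")
  missing <- setdiff(req, colnames(md))
  if (length(missing))
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  if (!all(md$tissue %in% c("blood", "gonad")))
    stop("unknown tissue token: ",
         paste(unique(setdiff(md$tissue, c("blood", "gonad"))), collapse = ", "))
  if (!all(md$sex %in% c("F", "M", "unknown")))
    stop("unknown sex token: ",
         paste(unique(setdiff(md$sex, c("F", "M", "unknown"))), collapse = ", "))
  if (any(md$sex == "unknown" & md$tissue != "gonad"))
    stop("sex may be 'unknown' only for gonad samples")
  temp <- suppressWarnings(as.numeric(md$temperature))
  if (anyNA(temp)) stop("non-numeric temperature value")
  if (any(temp < 25 | temp > 40))
    stop("temperature outside the plausible incubation range [25, 40]")
  md$temperature <- temp
  if (any(!nzchar(md$clutch))) stop("empty clutch identifier")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id")
  if (!"role" %in% colnames(md)) md$role <- "unassigned"
  md
}

#' Assemble per-sample calls into a MethylomeSE
#'
#' @param callsList named list (by sample id) of call data.frames.
#' @param metadata metadata `data.frame`; every sample in `callsList`
#'   must appear in `metadata$sample_id`.
#' @param locusPolicy `"union"` keeps every locus seen in any sample
#'   (absent cells `NA`); `"intersection"` keeps loci seen in all.
#' @return a [MethylomeSE] with deterministic locus ordering (scaffold
#'   lexicographic, then position) and columns in metadata order
#'   restricted to the supplied samples.
#' @export
buildMethylome <- function(callsList, metadata,
                           locusPolicy = c("union", "intersection")) {
  locusPolicy <- match.arg(locusPolicy)
  metadata <- validateSampleMetadata(metadata)
  if (!all(names(callsList) %in% metadata$sample_id))
    stop("sample(s) absent from metadata: ",
         paste(setdiff(names(callsList), metadata$sample_id), collapse = ", "))
  metadata <- metadata[match(intersect(metadata$sample_id, names(callsList)),
                             metadata$sample_id), , drop = FALSE]
  callsList <- callsList[metadata$sample_id]
  keys <- lapply(callsList, function(cc) paste0(cc$scaffold, ":", cc$pos))
  for (s in names(keys))
    if (anyDuplicated(keys[[s]]))
      stop("duplicate loci within sample ", s)
  allKeys <- if (locusPolicy == "union") unique(unlist(keys)) else
    Reduce(intersect, keys)
  parts <- strsplit(allKeys, ":", fixed = TRUE)
  scaffold <- vapply(parts, `[[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[[`, character(1), 2L))
  ord <- order(scaffold, pos, method = "radix")
  scaffold <- scaffold[ord]; pos <- pos[ord]; allKeys <- allKeys[ord]
  n <- length(allKeys)
  meth <- matrix(NA_integer_, n, length(callsList),
                 dimnames = list(NULL, names(callsList)))
  cov <- meth
  for (s in names(callsList)) {
    cc <- callsList[[s]]
    idx <- match(paste0(cc$scaffold, ":", cc$pos), allKeys)
    keep <- !is.na(idx)
    meth[idx[keep], s] <- cc$meth[keep]
    cov[idx[keep], s] <- cc$coverage[keep]
  }
  MethylomeSE(data.frame(scaffold = scaffold, pos = pos),
              meth, cov, sampleData = metadata)
}

#' Serialize / restore a MethylomeSE as TSV
#'
#' Plain-text round-trip format:
#' `scaffold  pos  <sample>:meth  <sample>:cov  ...` with `NA` for
#' missing cells. Sample metadata travels in a sibling `<path>.meta.tsv`.
#'
#' @param x a `MethylomeSE`.
#' @param path output TSV path.
#' @export
writeMethylome <- function(x, path) {
  m <- methCounts(x); cv <- covCounts(x)
  df <- data.frame(scaffold = as.character(seqnames(x)),
                   pos = lociPositions(x), check.names = FALSE)
  for (s in colnames(m)) {
    df[[paste0(s, ":meth")]] <- m[, s]
    df[[paste0(s, ":cov")]] <- cv[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(colData(x)), paste0(path, ".meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMethylome
#' @export
readMethylome <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  md <- utils::read.delim(paste0(path, ".meta.tsv"), sep = "\t",
                          stringsAsFactors = FALSE)
  samples <- md$sample_id
  meth <- as.matrix(df[paste0(samples, ":meth")])
  cov <- as.matrix(df[paste0(samples, ":cov")])
  colnames(meth) <- colnames(cov) <- samples
  MethylomeSE(data.frame(scaffold = df$scaffold, pos = df$pos),
              meth, cov, sampleData = md)
}
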