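#' Predict CpG islands by sliding-window GC and CpG observed/expected
#'
#' A 100-bp window slides by 1 bp over each scaffold. Per window,
#' GC% = 100 (C + G) / len and observed/expected CpG =
#' (N_CG * len) / (N_C * N_G) (0 when either base count is 0; N bases
#' count as neither C nor G and break CG dinucleotides). Every position
#' covered by at least one window meeting both thresholds is an island
#' candidate; maximal runs of candidates at least `minlen` long are
#' reported as islands.
#'
#' @param genome `DNAStringSet` (or FASTA path).
#' @param window window size in bp (default 100).
#' @param minlen minimum island length in bp (default 200).
#' @param minOE minimum observed/expected CpG ratio (default 0.6).
#' @param minGC minimum GC percentage (default 50).
#' @return `GRanges` of islands with seqlengths set.
#' @export
findCpGIslands <- function(genome, window = 100L, minlen = 200L,
                           minOE = 0.6, minGC = 50) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  res <- lapply(names(genome), function(sc) {
    s <- genome[[sc]]
    L <- length(s)
    if (L < window) return(IRanges())
    ch <- strsplit(as.character(s), "", fixed = TRUE)[[1L]]
    isC <- ch == "C"; isG <- ch == "G"
    isCG <- c(isC[-L] & isG[-1L], FALSE)
    cumC <- cumsum(isC); cumG <- cumsum(isG); cumCG <- cumsum(isCG)
    starts <- seq_len(L - window + 1L)
    nC <- cumC[starts + window - 1L] - c(0, cumC)[starts]
    nG <- cumG[starts + window - 1L] - c(0, cumG)[starts]
    nCG <- cumCG[starts + window - 2L] - c(0, cumCG)[starts]
    gcPct <- 100 * (nC + nG) / window
    oe <- ifelse(nC * nG > 0, (nCG * window) / (nC * nG), 0)
    pass <- gcPct >= minGC & oe >= minOE
    if (!any(pass)) return(IRanges())
    # union of [i, i + window - 1] over passing windows, via coverage delta
    ps <- starts[pass]
    add <- tabulate(ps, nbins = L)
    rem <- tabulate(ps + window, nbins = L + 1L)
    cov <- cumsum(add - rem[seq_len(L)])
    r <- rle(cov > 0L)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minlen
    IRanges(begs[keep], ends[keep])
  })
  names(res) <- names(genome)
  gr <- GRanges(rep(names(res), vapply(res, length, integer(1))),
                unlist(IRanges::IRangesList(res), use.names = FALSE))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- sl
  gr
}

#' Partition the genome into island / shore / shelf / open-sea classes
#'
#' Shores are the 2000-bp flanks of islands (minus islands), shelves
#' the 2000-bp flanks of shores (minus shores and islands), open sea
#' the remainder; all clipped at scaffold edges. The four classes
#' partition every scaffold.
#'
#' @param islands `GRanges` from [findCpGIslands()], with seqlengths.
#' @param flank flank width in bp (default 2000).
#' @return named list of `GRanges`: `islands`, `shores`, `shelves`,
#'   `open_sea`.
#' @export
cgiAnnotation <- function(islands, flank = 2000L) {
  if (anyNA(GenomeInfoDb::seqlengths(islands)))
    stop("islands must carry seqlengths")
  isl <- GenomicRanges::reduce(islands)
  ext1 <- suppressWarnings(GenomicRanges::trim(isl + flank))
  shores <- GenomicRanges::setdiff(ext1, isl)
  ext2 <- suppressWarnings(GenomicRanges::trim(ext1 + flank))
  shelves <- GenomicRanges::setdiff(ext2, GenomicRanges::union(isl, shores))
  genomeGr <- GRanges(GenomeInfoDb::seqlevels(islands),
                      IRanges(1L, GenomeInfoDb::seqlengths(islands)))
  openSea <- GenomicRanges::setdiff(genomeGr, ext2)
  list(islands = isl, shores = shores, shelves = shelves, open_sea = openSea)
}

#' CpG-island context of loci
#'
#' @param loci `GRanges` (or a [MethylomeSE]).
#' @param cgi list from [cgiAnnotation()].
#' @return character vector: island / shore / shelf / open_sea
#'   (precedence in that order).
#' @export
cgiContext <- function(loci, cgi) {
  if (is(loci, "MethylomeSE")) loci <- granges(loci)
  out <- rep("open_sea", length(loci))
  out[IRanges::overlapsAny(loci, cgi$shelves)] <- "shelf"
  out[IRanges::overlapsAny(loci, cgi$shores)] <- "shore"
  out[IRanges::overlapsAny(loci, cgi$islands)] <- "island"
  out
}

#' Build gene models from a gene table
#'
#' The table uses 0-based half-open coordinates: columns `gene_id`,
#' `scaffold`, `strand`, `tx_start`, `tx_end`, and comma-separated
#' `exon_starts` / `exon_ends`. Promoters are strand-aware windows
#' around the transcription start site (default 1000 bp upstream,
#' 200 bp downstream) — the promoter window is a convention, not a
#' property of the annotation, and shifts promoter-enrichment results.
#'
#' @param geneTable data.frame (or TSV path).
#' @param promoterUp,promoterDown promoter window around the TSS in bp.
#' @return list with `genes` (GRanges, gene spans), `exons`
#'   (GRangesList by gene) and `promoters` (GRanges).
#' @export
geneModels <- function(geneTable, promoterUp = 1000L, promoterDown = 200L) {
  if (is.character(geneTable))
    geneTable <- utils::read.delim(geneTable, stringsAsFactors = FALSE)
  gt <- geneTable
  stopifnot(all(gt$tx_end > gt$tx_start), all(gt$strand %in% c("+", "-")))
  genes <- GRanges(gt$scaffold, IRanges(gt$tx_start + 1L, gt$tx_end),
                   strand = gt$strand, gene_id = gt$gene_id)
  exons <- lapply(seq_len(nrow(gt)), function(i) {
    es <- as.integer(strsplit(as.character(gt$exon_starts[i]), ",")[[1L]])
    ee <- as.integer(strsplit(as.character(gt$exon_ends[i]), ",")[[1L]])
    stopifnot(length(es) == length(ee), all(ee > es),
              all(es >= gt$tx_start[i]), all(ee <= gt$tx_end[i]))
    GRanges(gt$scaffold[i], IRanges(es + 1L, ee), strand = gt$strand[i])
  })
  names(exons) <- gt$gene_id
  proms <- GenomicRanges::promoters(genes, upstream = promoterUp,
                                    downstream = promoterDown)
  proms <- GenomicRanges::trim(proms)
  list(genes = genes, exons = GenomicRanges::GRangesList(exons),
       promoters = proms)
}

#' Gene context of loci with precedence
#'
#' Precedence promoter > exon > intron > intergenic; a locus inside a
#' gene span but not in any exon is intronic. Exactly one class per
#' locus.
#'
#' @param loci `GRanges` (or [MethylomeSE]).
#' @param gm gene models from [geneModels()].
#' @return character vector of contexts.
#' @export
geneContext <- function(loci, gm) {
  if (is(loci, "MethylomeSE")) loci <- granges(loci)
  out <- rep("intergenic", length(loci))
  inGene <- IRanges::overlapsAny(loci, gm$genes, ignore.strand = TRUE)
  out[inGene] <- "intron"
  inExon <- IRanges::overlapsAny(loci, unlist(gm$exons), ignore.strand = TRUE)
  out[inExon] <- "exon"
  inProm <- IRanges::overlapsAny(loci, gm$promoters, ignore.strand = TRUE)
  out[inProm] <- "promoter"
  out
}

#' Nearest gene per locus
#'
#' Distance is 0 inside the gene span; ties are broken by lower gene
#' start, then lexicographic gene id. Loci on scaffolds without genes
#' get `NA` distance.
#'
#' @param loci `GRanges` (or [MethylomeSE]).
#' @param gm gene models from [geneModels()].
#' @return data.frame with `gene_id` and `distance` (bp).
#' @export
nearestGene <- function(loci, gm) {
  if (is(loci, "MethylomeSE")) loci <- granges(loci)
  genes <- gm$genes
  # candidates: overlapping genes (distance 0) plus the nearest
  # preceding and following gene; equidistant candidates are resolved
  # by lower gene start, then lexicographic id
  ov <- GenomicRanges::findOverlaps(loci, genes, ignore.strand = TRUE)
  cand <- data.frame(q = S4Vectors::queryHits(ov),
                     s = S4Vectors::subjectHits(ov),
                     d = rep(0, length(ov)))
  up <- GenomicRanges::follow(loci, genes, ignore.strand = TRUE)
  qs <- which(!is.na(up))
  if (length(qs))
    cand <- rbind(cand, data.frame(
      q = qs, s = up[qs],
      d = start(loci)[qs] - GenomicRanges::end(genes)[up[qs]] - 1L))
  dn <- GenomicRanges::precede(loci, genes, ignore.strand = TRUE)
  qs <- which(!is.na(dn))
  if (length(qs))
    cand <- rbind(cand, data.frame(
      q = qs, s = dn[qs],
      d = start(genes)[dn[qs]] - GenomicRanges::end(loci)[qs] - 1L))
  cand$gstart <- start(genes)[cand$s]
  cand$gid <- genes$gene_id[cand$s]
  cand <- cand[order(cand$q, cand$d, cand$gstart, cand$gid), ]
  cand <- cand[!duplicated(cand$q), ]
  out <- data.frame(gene_id = rep(NA_character_, length(loci)),
                    distance = rep(NA_real_, length(loci)),
                    stringsAsFactors = FALSE)
  out$gene_id[cand$q] <- cand$gid
  out$distance[cand$q] <- cand$d
  out
}

#' Tile the genome into 1-kb windows of CpG density
#'
#' Counts CG dinucleotide start positions per non-overlapping 1-kb tile
#' (the last, possibly shorter, tile of each scaffold included) and
#' assigns a density bin of width 20 CpG/kb (`floor(count / 20)`).
#'
#' @param genome `DNAStringSet` (or FASTA path).
#' @param tileWidth tile width in bp (default 1000).
#' @param binWidth bin width in CpG per tile (default 20).
#' @return `GRanges` of tiles with metadata `cpg_count`, `density_bin`.
#' @export
tileCpGDensity <- function(genome, tileWidth = 1000L, binWidth = 20L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  res <- lapply(names(genome), function(sc) {
    L <- length(genome[[sc]])
    starts <- seq(1L, L, by = tileWidth)
    ends <- pmin(starts + tileWidth - 1L, L)
    cg <- Biostrings::start(Biostrings::matchPattern("CG", genome[[sc]]))
    counts <- as.integer(table(factor(findInterval(cg, starts),
                                      levels = seq_along(starts))))
    GRanges(factor(sc, levels = names(genome)), IRanges(starts, ends),
            cpg_count = counts, density_bin = counts %/% binWidth)
  })
  out <- do.call(c, res)
  GenomeInfoDb::seqlengths(out) <-
    stats::setNames(Biostrings::width(genome), names(genome))
  out
}

#' Bin loci by overall mean percent methylation
#'
#' Mean over non-missing samples, cut into right-closed 20-point bins
#' (0 falls in the first bin); all-missing loci get `NA`.
#'
#' @param pm percent matrix (loci x samples) or a [MethylomeSE].
#' @return factor with levels `0-20`, ..., `80-100`.
#' @export
meanMethBin <- function(pm) {
  if (is(pm, "MethylomeSE")) pm <- percentMeth(pm)
  mu <- rowMeans(pm, na.rm = TRUE)
  mu[!is.finite(mu)] <- NA
  idx <- pmin(pmax(ceiling(mu / 20), 1L), 5L)
  labs <- c("0-20", "20-40", "40-60", "60-80", "80-100")
  factor(labs[idx], levels = labs)
}

#' Per-category Fisher enrichment of DMCs against a background
#'
#' For each annotation category a 2x2 table (in/out of category x
#' DMC/background) is tested with a two-sided Fisher exact test; BH
#' adjustment across categories. The background should exclude the
#' DMCs being tested.
#'
#' @param dmcCounts named integer vector of DMCs per category.
#' @param backgroundCounts named integer vector of background loci per
#'   category (same names).
#' @return data.frame with `category`, `odds_ratio`, `p`, `q`.
#' @export
enrichmentTest <- function(dmcCounts, backgroundCounts) {
  cats <- names(dmcCounts)
  stopifnot(!is.null(cats), setequal(cats, names(backgroundCounts)))
  backgroundCounts <- backgroundCounts[cats]
  nD <- sum(dmcCounts); nB <- sum(backgroundCounts)
  res <- lapply(cats, function(cat) {
    tab <- matrix(c(dmcCounts[[cat]], nD - dmcCounts[[cat]],
                    backgroundCounts[[cat]], nB - backgroundCounts[[cat]]),
                  nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(data.frame(category = cat, odds_ratio = NA_real_, p = 1))
    ft <- stats::fisher.test(tab)
    data.frame(category = cat, odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out
}
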