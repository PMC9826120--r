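test_that("CpG-island prediction matches the per-position window oracle", {
  polyA <- strrep("A", 300)
  expect_equal(length(findCpGIslands(Biostrings::DNAStringSet(c(s = polyA)))),
               0L)
  # a CG tract flanked by poly-A yields exactly one island over the tract
  tract <- strrep("CG", 120)
  seqs <- c(one = paste0(strrep("A", 200), tract, strrep("A", 200)))
  isl <- findCpGIslands(Biostrings::DNAStringSet(seqs))
  expect_equal(length(isl), 1L)
  expect_gte(IRanges::width(isl), 200)
  orc <- oracleCgi(seqs[[1]])
  expect_equal(GenomicRanges::start(isl), unname(orc[, "start"]))
  expect_equal(GenomicRanges::end(isl), unname(orc[, "end"]))
  # O/E for a pure CG repeat: (120 * 240) / (120 * 120) = 2
  ch <- strsplit(tract, "")[[1]]
  expect_equal((sum(ch[-240] == "C" & ch[-1] == "G") * 240) /
                 (sum(ch == "C") * sum(ch == "G")), 2)
})

test_that("island prediction equals the oracle on random sequences", {
  set.seed(19)
  for (rep in 1:4) {
    # random sequence with a couple of GC-rich patches
    base <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3))
    for (st in sample(seq(200, 3400, by = 700), 2)) {
      patch <- sample(c("C", "G", "A"), 350, replace = TRUE,
                      prob = c(0.42, 0.42, 0.16))
      base[st:(st + 349)] <- patch
    }
    base[sample(4000, 20)] <- "N"
    s <- paste(base, collapse = "")
    isl <- findCpGIslands(Biostrings::DNAStringSet(c(x = s)))
    orc <- oracleCgi(s)
    expect_equal(GenomicRanges::start(isl), unname(orc[, "start"]))
    expect_equal(GenomicRanges::end(isl), unname(orc[, "end"]))
  }
})

test_that("island, shore, shelf and open sea partition the genome", {
  cfg <- simulationConfig(seed = 23)
  g <- simulateGenome(cfg)
  isl <- findCpGIslands(g$genome)
  ann <- cgiAnnotation(isl)
  total <- sum(vapply(ann, function(x) sum(IRanges::width(x)), numeric(1)))
  expect_equal(total, sum(Biostrings::width(g$genome)))
  # no class overlaps another
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(length(GenomicRanges::intersect(ann[[i]], ann[[j]])), 0L)
})

test_that("CGI context follows island > shore > shelf precedence", {
  isl <- GenomicRanges::GRanges("s", IRanges::IRanges(10001, 10400))
  GenomeInfoDb::seqlengths(isl) <- c(s = 50000)
  ann <- cgiAnnotation(isl)
  at <- function(pos) cgiContext(
    GenomicRanges::GRanges("s", IRanges::IRanges(pos, pos)), ann)
  expect_equal(at(10200), "island")
  expect_equal(at(10400 + 1500), "shore")
  expect_equal(at(10400 + 3500), "shelf")
  expect_equal(at(10400 + 4500), "open_sea")
})

test_that("gene context applies promoter > exon > intron > intergenic", {
  gt <- data.frame(
    gene_id = c("geneA", "geneB"),
    scaffold = "s",
    strand = c("+", "+"),
    tx_start = c(5000L, 3500L),
    tx_end = c(8000L, 6000L),
    exon_starts = c("5000,7000", "3500,5900"),
    exon_ends = c("5500,8000", "3600,6000"))
  gm <- geneModels(gt)
  at <- function(pos0) geneContext(
    GenomicRanges::GRanges("s", IRanges::IRanges(pos0 + 1, pos0 + 1)), gm)
  # in geneA's promoter (TSS 5000, window -1000/+200) and geneB's intron
  expect_equal(at(4500), "promoter")
  # at an exon's half-open end (exon [5000,5500) ends at 5499): 5500 is
  # inside the gene but outside the exon -> intron
  expect_equal(at(5499), "exon")
  expect_equal(at(5500), "intron")
  expect_equal(at(20000), "intergenic")
  # gene-free scaffold (seqlevel-mismatch warnings are expected here)
  expect_equal(suppressWarnings(geneContext(
    GenomicRanges::GRanges("other", IRanges::IRanges(5, 5)), gm)),
    "intergenic")
})

test_that("nearest gene distance uses half-open arithmetic and tie-breaks", {
  gt <- data.frame(gene_id = c("gA", "gB"), scaffold = "s", strand = "+",
                   tx_start = c(1000L, 4000L), tx_end = c(2000L, 5000L),
                   exon_starts = c("1000", "4000"),
                   exon_ends = c("2000", "5000"))
  gm <- geneModels(gt)
  at <- function(pos0) nearestGene(
    GenomicRanges::GRanges("s", IRanges::IRanges(pos0 + 1, pos0 + 1)), gm)
  expect_equal(at(1500)$distance, 0)
  expect_equal(at(2500)$distance, 500)       # 2500 - 2000 (half-open)
  # an exactly equidistant locus takes the deterministic tie-break
  gt2 <- gt; gt2$tx_start <- c(1000L, 3001L); gt2$tx_end <- c(2000L, 4001L)
  gt2$exon_starts <- c("1000", "3001"); gt2$exon_ends <- c("2000", "4001")
  gm2 <- geneModels(gt2)
  res <- nearestGene(
    GenomicRanges::GRanges("s", IRanges::IRanges(2501, 2501)), gm2)
  expect_equal(res$distance, 500)
  expect_equal(res$gene_id, "gA")            # lower start wins
})

test_that("density tiles count CG starts and conserve the total", {
  s1 <- strrep("A", 1000)
  s2 <- paste0(strrep("CG", 500))
  g <- Biostrings::DNAStringSet(c(a = s1, b = s2))
  tiles <- tileCpGDensity(g)
  expect_equal(tiles$cpg_count[as.character(GenomicRanges::seqnames(tiles))
                               == "a"], 0L)
  bTile <- tiles[as.character(GenomicRanges::seqnames(tiles)) == "b"]
  expect_equal(bTile$cpg_count, 500L)
  expect_equal(bTile$density_bin, 25L)
  cfg <- simulationConfig(seed = 29)
  gen <- simulateGenome(cfg)$genome
  tl <- tileCpGDensity(gen)
  direct <- sum(vapply(names(gen), function(sc)
    length(Biostrings::matchPattern("CG", gen[[sc]])), integer(1)))
  expect_equal(sum(tl$cpg_count), direct)
})

test_that("mean-methylation bins are right-closed with 0 in the first bin", {
  pm <- rbind(c(90, 90), c(20, 20), c(0, 0), c(20.5, 20.5), c(NA, NA))
  bins <- meanMethBin(pm)
  expect_equal(as.character(bins),
               c("80-100", "0-20", "0-20", "20-40", NA))
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  res <- enrichmentTest(c(x = 5, y = 5), c(x = 5, y = 5))
  expect_equal(res$odds_ratio, c(1, 1))
  expect_equal(res$p, c(1, 1))
  res2 <- enrichmentTest(c(x = 8, y = 2), c(x = 2, y = 8))
  expect_equal(res2$p[1], oracleFisher(8, 2, 2, 8), tolerance = 1e-9)
  # swapping the two categories inverts the OR, p unchanged
  res3 <- enrichmentTest(c(y = 2, x = 8), c(y = 8, x = 2))
  expect_equal(res3$odds_ratio[res3$category == "x"],
               res2$odds_ratio[res2$category == "x"])
  expect_equal(sort(res3$p), sort(res2$p))
  # random tables against the oracle
  set.seed(4)
  for (rep in 1:10) {
    a <- rpois(1, 6); b <- rpois(1, 6) + 1; c <- rpois(1, 6) + 1
    d <- rpois(1, 6) + 1
    r <- enrichmentTest(c(in_ = a, out = b), c(in_ = c, out = d))
    expect_equal(r$p[1], oracleFisher(a, b, c, d), tolerance = 1e-8)
  }
})

test_that("planted island enrichment of DMCs is detected", {
  set.seed(41)
  cfg <- simulationConfig(seed = 41)
  g <- simulateGenome(cfg)
  isl <- findCpGIslands(g$genome)
  ann <- cgiAnnotation(isl)
  idx <- cpgIndex(g$genome)
  all <- do.call(rbind, lapply(names(idx), function(sc)
    data.frame(scaffold = sc, pos = idx[[sc]])))
  gr <- GenomicRanges::GRanges(all$scaffold,
                               IRanges::IRanges(all$pos + 1, width = 1))
  ctx <- cgiContext(gr, ann)
  inIsl <- which(ctx == "island"); outIsl <- which(ctx != "island")
  # DMCs drawn almost exclusively from islands
  dmc <- c(sample(inIsl, 38), sample(outIsl, 2))
  bg <- setdiff(seq_along(ctx), dmc)
  counts <- function(ix) table(factor(ctx[ix] == "island",
                                      levels = c(TRUE, FALSE)))
  dc <- counts(dmc); bc <- counts(bg)
  res <- enrichmentTest(c(island = dc[[1]], other = dc[[2]]),
                        c(island = bc[[1]], other = bc[[2]]))
  expect_gt(res$odds_ratio[1], 1)
  expect_lt(res$p[1], 0.05)
})
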