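test_that("bismark coverage lines parse with the 1-based to 0-based shift", {
  f <- withr::local_tempfile()
  writeLines(c("scaf1\t101\t101\t75\t3\t1",
               "scaf1\t205\t205\t0\t0\t8"), f)
  calls <- readBismarkCoverage(f)
  expect_equal(calls$pos, c(100L, 204L))
  expect_equal(calls$meth, c(3L, 0L))
  expect_equal(calls$unmeth, c(1L, 8L))
  expect_equal(calls$coverage, c(4L, 8L))
})

test_that("empty, discrepant and malformed coverage files are handled", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  expect_equal(nrow(readBismarkCoverage(f)), 0L)
  # percent column disagrees with counts (100*3/4 = 75, not 50)
  writeLines("scaf1\t101\t101\t50\t3\t1", f)
  expect_warning(calls <- readBismarkCoverage(f), "0.5")
  expect_equal(calls$meth, 3L)   # call retained
  writeLines("scaf1\t101\t101", f)
  expect_error(readBismarkCoverage(f), "malformed")
  writeLines("scaf1\t101\t101\t75\t-3\t1", f)
  expect_error(readBismarkCoverage(f), "negative")
})

test_that("strand merging sums counts at the plus-strand C", {
  calls <- data.frame(scaffold = "s1", pos = c(100L, 101L),
                      meth = c(3L, 2L), unmeth = c(1L, 2L),
                      coverage = c(4L, 4L))
  idx <- list(s1 = c(100L, 300L))
  merged <- mergeStrands(calls, idx)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$pos, 100L)
  expect_equal(merged$meth, 5L)
  expect_equal(merged$coverage, 8L)
  # plus-only call passes through unchanged
  solo <- data.frame(scaffold = "s1", pos = 300L, meth = 1L,
                     unmeth = 0L, coverage = 1L)
  expect_equal(mergeStrands(solo, idx)$pos, 300L)
  # a call matching no reference CpG is flagged and dropped
  orphan <- rbind(calls, data.frame(scaffold = "s1", pos = 500L,
                                    meth = 2L, unmeth = 0L, coverage = 2L))
  expect_warning(m2 <- mergeStrands(orphan, idx), "no reference CpG")
  expect_equal(sum(m2$coverage), 8L)
})

test_that("strand merging conserves total counts on random fixtures", {
  set.seed(42)
  for (rep in 1:5) {
    cpg <- sort(sample(seq(10L, 5000L, by = 4L), 200L))
    pick <- sort(sample(cpg, 120L))
    withMinus <- runif(120) < 0.5
    rows <- list()
    for (i in seq_along(pick)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = "s1", pos = pick[i],
        meth = rpois(1, 5), unmeth = rpois(1, 5))
      if (withMinus[i])
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = "s1", pos = pick[i] + 1L,
          meth = rpois(1, 5), unmeth = rpois(1, 5))
    }
    calls <- do.call(rbind, rows)
    calls$coverage <- calls$meth + calls$unmeth
    merged <- mergeStrands(calls, list(s1 = cpg))
    expect_equal(sum(merged$meth), sum(calls$meth))
    expect_equal(sum(merged$coverage), sum(calls$coverage))
    expect_true(all(merged$pos %in% cpg))
    # with a plus-strand call at every covered CpG and CpGs >= 3 bp
    # apart, the reference-free adjacency pairing is exact
    expect_equal(mergeStrands(calls), merged)
  }
})

test_that("matrix assembly respects locus policy and sample order", {
  mkCalls <- function(pos) data.frame(scaffold = "s1", pos = pos,
                                      meth = seq_along(pos),
                                      unmeth = 1L,
                                      coverage = seq_along(pos) + 1L)
  md <- data.frame(sample_id = c("a", "b"), tissue = "blood",
                   sex = c("F", "M"), temperature = c(30, 33.5),
                   clutch = "c1")
  calls <- list(a = mkCalls(c(10L, 20L, 30L, 40L)),
                b = mkCalls(c(10L, 20L, 30L, 50L)))
  un <- buildMethylome(calls, md, "union")
  expect_equal(nrow(un), 5L)
  expect_equal(sum(is.na(covCounts(un))), 2L)
  inter <- buildMethylome(calls, md, "intersection")
  expect_equal(nrow(inter), 3L)
  single <- buildMethylome(calls["a"], md)
  expect_equal(ncol(single), 1L)
  # permuting input samples permutes columns only
  un2 <- buildMethylome(rev(calls), md)
  expect_equal(covCounts(un2)[, c("a", "b")], covCounts(un)[, c("a", "b")])
  dup <- calls
  dup$a <- rbind(dup$a, dup$a[1L, ])
  expect_error(buildMethylome(dup, md), "duplicate loci")
})

test_that("sample metadata is validated", {
  f <- withr::local_tempfile()
  writeLines(c("sample_id\ttissue\tsex\ttemperature\tclutch",
               "B01\tblood\tF\t30\tAP-03",
               "G01\tgonad\tunknown\t33.5\tAP-04"), f)
  md <- readSampleMetadata(f)
  expect_equal(md$sex, c("F", "unknown"))
  expect_equal(md$temperature, c(30, 33.5))
  writeLines(c("sample_id\ttissue\tsex\ttemperature\tclutch",
               "B01\tblood\tF\tthirty\tAP-03"), f)
  expect_error(readSampleMetadata(f), "temperature")
  writeLines(c("sample_id\ttissue\tsex\ttemperature\tclutch",
               "B01\tblood\tunknown\t30\tAP-03"), f)
  expect_error(readSampleMetadata(f), "gonad")
  writeLines(c("sample_id\ttissue\tsex\ttemperature\tclutch",
               "B01\tblood\tX\t30\tAP-03"), f)
  expect_error(readSampleMetadata(f), "sex")
})

test_that("matrix serialisation round-trips counts bit-exactly", {
  set.seed(7)
  cfg <- simulationConfig(seed = 7, nLoci = 120)
  sim <- simulateMethylomes(cfg)
  f <- withr::local_tempfile()
  writeMethylome(sim$se, f)
  back <- readMethylome(f)
  expect_identical(methCounts(back), methCounts(sim$se))
  expect_identical(covCounts(back), covCounts(sim$se))
  expect_equal(lociKeys(back), lociKeys(sim$se))
})

test_that("simulated strand-split coverage files reassemble to the matrix", {
  dir <- withr::local_tempdir()
  cfg <- simulationConfig(seed = 9, nLoci = 150)
  sim <- simulateMethylomes(cfg, dir = dir, splitStrands = TRUE)
  md <- readSampleMetadata(file.path(dir, "metadata.tsv"))
  calls <- lapply(stats::setNames(md$sample_id, md$sample_id), function(s)
    mergeStrands(readBismarkCoverage(file.path(dir, paste0(s, ".cov")))))
  rebuilt <- buildMethylome(calls, md, "union")
  common <- intersect(lociKeys(rebuilt), lociKeys(sim$se))
  expect_true(length(common) > 100)
  i1 <- match(common, lociKeys(rebuilt)); i2 <- match(common, lociKeys(sim$se))
  m1 <- methCounts(rebuilt)[i1, md$sample_id]
  m2 <- methCounts(sim$se)[i2, md$sample_id]
  expect_equal(unname(m1), unname(m2))
})
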