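# Probe filtering, segmentation, calling and recurrence scoring.

probesFrom <- function(logR, chrom = "chr1", sample = "S01", spacing = 1e4,
                       baf = NA_real_) {
  data.frame(sample = sample, probe = sprintf("P%04d", seq_along(logR)),
             chrom = chrom, pos = spacing * seq_along(logR),
             logR = logR, baf = baf)
}

test_that("probes missing in any sample are dropped everywhere", {
  p <- rbind(probesFrom(c(0, NA, 0), sample = "A"),
             probesFrom(c(0, 0, 0), sample = "B"),
             probesFrom(c(0, 0, 0), sample = "C"))
  out <- filterProbes(p)
  expect_equal(sort(unique(out$probe)), c("P0001", "P0003"))
  expect_equal(nrow(out), 6L)
  # no missing values: identity
  q <- rbind(probesFrom(c(0, 1), sample = "A"),
             probesFrom(c(0, 1), sample = "B"))
  expect_identical(filterProbes(q), q)
  # all probes missing in one sample: empty output
  r <- rbind(probesFrom(c(NA_real_, NA_real_), sample = "A"),
             probesFrom(c(0, 0), sample = "B"))
  expect_equal(nrow(filterProbes(r)), 0L)
})

test_that("segmentation recovers a noiseless step exactly", {
  y <- c(rep(0, 20), rep(-1, 15))
  segs <- segmentProfile(probesFrom(y), penalty = 0.5)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_probes, c(20L, 15L))
  expect_equal(segs$mean_logR, c(0, -1))
  # segments tile the probed span, cut between probes 20 and 21
  expect_equal(segs$start[1], 1e4 - 1)
  expect_equal(segs$end[1], segs$start[2])
  expect_equal(segs$end[2], 35e4)

  # constant profile: one segment for any positive penalty
  flat <- segmentProfile(probesFrom(rep(0.3, 30)), penalty = 1e-4)
  expect_equal(nrow(flat), 1L)
  # penalty -> infinity: one segment per chromosome
  big <- segmentProfile(probesFrom(y), penalty = 1e9)
  expect_equal(nrow(big), 1L)
  expect_equal(big$n_probes, 35L)

  expect_error(segmentProfile(probesFrom(y)[c(2, 1, 3:35), ]), "sorted")
})

test_that("DP segmentation equals exhaustive breakpoint search", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    k <- sample(0:3, 1)
    bk <- sort(sample(seq_len(n - 1), k))
    means <- stats::runif(k + 1, -1.5, 1.5)
    y <- rep(means, diff(c(0, bk, n))) + stats::rnorm(n, 0, 0.2)
    pen <- stats::runif(1, 0.1, 2)
    dp <- mesoscape:::segmentSeries(y, pen)
    oracle <- exhaustiveSegment(y, pen, maxBreaks = 3)
    dpBreaks <- dp[-nrow(dp), "end"]
    dpCost <- sum(vapply(seq_len(nrow(dp)), function(i) {
      v <- y[dp[i, "start"]:dp[i, "end"]]
      sum((v - mean(v))^2)
    }, numeric(1))) + pen * (nrow(dp) - 1)
    # the DP may legitimately use >3 breakpoints; its cost is never worse
    expect_lte(dpCost, oracle$cost + 1e-9)
    if (nrow(dp) - 1 <= 3) {
      expect_equal(dpCost, oracle$cost, tolerance = 1e-9)
    }
  }
})

test_that("segment count is non-increasing in the penalty", {
  set.seed(7)
  y <- rep(c(0, -0.8, 0.4, 0), times = c(25, 20, 15, 25)) +
    stats::rnorm(85, 0, 0.15)
  pens <- c(0.05, 0.2, 0.8, 3, 12, 50)
  counts <- vapply(pens, function(p) {
    nrow(segmentProfile(probesFrom(y), penalty = p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # probe conservation and ordered disjoint spans at every penalty
  for (p in pens) {
    s <- segmentProfile(probesFrom(y), penalty = p)
    expect_equal(sum(s$n_probes), 85L)
    expect_true(all(s$end > s$start))
    expect_true(all(s$start[-1] == s$end[-nrow(s)]))
  }
})

test_that("status and LOH thresholds are strict", {
  s <- segRow(mean_logR = 0.25)
  expect_equal(s$status, "neutral")
  expect_equal(segRow(mean_logR = 0.30)$status, "amplified")
  expect_equal(segRow(mean_logR = -0.25)$status, "neutral")
  d <- segRow(mean_logR = -0.60, mean_mirrored_baf = 0.80)
  expect_equal(d$status, "deleted")
  expect_true(d$loh)
  expect_false(segRow(mean_logR = 0, mean_mirrored_baf = 0.55)$loh)
  expect_false(segRow(mean_logR = 0, mean_mirrored_baf = NA)$loh)
})

test_that("per-sample burden counts only large segments", {
  segs <- rbind(segRow(start = 0, end = 15e6, mean_logR = -0.6),
                segRow(start = 15e6, end = 15.5e6, mean_logR = -0.6),
                segRow(start = 20e6, end = 30e6, mean_logR = 0))
  out <- summarizeSample(segs)
  expect_equal(out$bp_lost, 15e6)
  expect_equal(out$n_lost, 1L)
  expect_equal(out$bp_gained, 0)
  # no non-neutral segments
  none <- summarizeSample(segRow(mean_logR = 0))
  expect_equal(unlist(none[, -1], use.names = FALSE), c(0, 0, 0, 0))
  # whole 50 Mb chromosome lost
  whole <- summarizeSample(segRow(start = 0, end = 5e7, mean_logR = -0.7))
  expect_equal(whole$bp_lost, 5e7)
})

test_that("cytoband fractions follow interval intersection with strict 75%", {
  bands <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1, 1e7), band = "1p1")
  seg8 <- segRow(start = 1e6, end = 9e6, mean_logR = -0.6)
  out <- callCytobands(seg8, bands)
  expect_equal(out$fraction_deleted, 0.8)
  expect_equal(out$status, "deleted")
  # exactly 7.5 Mb: "more than 75%" is strict -> neutral
  out2 <- callCytobands(segRow(start = 0, end = 7.5e6, mean_logR = -0.6),
                        bands)
  expect_equal(out2$fraction_deleted, 0.75)
  expect_equal(out2$status, "neutral")
  # band fully inside a deleted segment
  out3 <- callCytobands(segRow(start = 0, end = 2e7, mean_logR = -0.6),
                        bands)
  expect_equal(out3$fraction_deleted, 1)
  expect_equal(out3$status, "deleted")
})

test_that("cytoband fractions are invariant to splitting a segment", {
  bands <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1, 1e7), band = "1p1")
  whole <- segRow(start = 1e6, end = 9e6, mean_logR = -0.6)
  split <- rbind(segRow(start = 1e6, end = 4e6, mean_logR = -0.6),
                 segRow(start = 4e6, end = 9e6, mean_logR = -0.6))
  expect_equal(callCytobands(split, bands)$fraction_deleted,
               callCytobands(whole, bands)$fraction_deleted)
})

test_that("recurrent cytobands count deleted-or-strong-LOH samples", {
  bands <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1, 1e7), band = "1p1")
  del <- function(sm) segRow(sample = sm, start = 0, end = 1e7,
                             mean_logR = -0.6, mean_mirrored_baf = 0.8)
  neu <- function(sm) segRow(sample = sm, start = 0, end = 1e7,
                             mean_logR = 0)
  # copy-neutral LOH: neutral logR but high mirrored BAF
  cnLoh <- segRow(sample = "S4", start = 0, end = 1e7, mean_logR = 0,
                  mean_mirrored_baf = 0.9)
  segs <- rbind(del("S1"), del("S2"), del("S3"), cnLoh,
                do.call(rbind, lapply(paste0("S", 5:9), neu)))
  calls <- callCytobands(segs, bands)
  rec <- recurrentCytobands(calls, minSamples = 3)
  expect_equal(rec$band, "1p1")
  expect_equal(rec$n_samples, 4L)  # 3 deletions + 1 strong LOH
  # threshold relaxation
  rec1 <- recurrentCytobands(callCytobands(del("S1"), bands),
                             minSamples = 1)
  expect_equal(rec1$n_samples, 1L)
  # no alterations anywhere
  recN <- recurrentCytobands(callCytobands(neu("S1"), bands))
  expect_equal(nrow(recN), 0L)
})

test_that("gene scores sum segment means with neutral baselines", {
  genesGr <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(4e6, 5e6),
                                                     c(4.5e6, 5.5e6)),
                                    gene = c("G1", "G2"))
  del <- function(sm) segRow(sample = sm, start = 0, end = 1e7,
                             mean_logR = -0.6, mean_mirrored_baf = 0.8)
  neu <- function(sm) segRow(sample = sm, start = 0, end = 1e7,
                             mean_logR = 0, mean_mirrored_baf = 0.5)
  segs <- rbind(do.call(rbind, lapply(paste0("S", 1:5), del)),
                do.call(rbind, lapply(paste0("S", 6:9), neu)))
  gs <- geneScores(segs, genesGr)
  expect_equal(gs$net_logR, c(-3, -3))
  expect_equal(gs$net_baf, c(5 * 0.8 + 4 * 0.5, 5 * 0.8 + 4 * 0.5))
  # genes in the same segment in every sample score identically
  expect_equal(gs$net_logR[1], gs$net_logR[2])
  # all neutral: identity 0; uncovered sample contributes 0 and 0.5
  gsN <- geneScores(do.call(rbind, lapply(paste0("S", 1:3), neu)), genesGr)
  expect_equal(gsN$net_logR, c(0, 0))
  expect_equal(gsN$net_baf, c(1.5, 1.5))
  short <- segRow(sample = "S1", start = 0, end = 1e6, mean_logR = -0.6)
  gsU <- geneScores(short, genesGr)  # gene midpoints not covered
  expect_equal(gsU$net_logR, c(0, 0))
  expect_equal(gsU$net_baf, c(0.5, 0.5))
  expect_error(
    geneScores(segs, GenomicRanges::GRanges("chrX",
                                            IRanges::IRanges(1, 10),
                                            gene = "GX")),
    "unknown chromosome")
})

test_that("BAF-guided recentring exposes a whole-chromosome loss", {
  gm <- makeGenome(c(chr1 = 2e7, chr2 = 2e7, chr3 = 1e7), bandsPerChrom = 2,
                   genesPerChrom = 0, seed = 4)
  tr <- TruthSet(purity = 0.7, cnEvents = data.frame(
    sample = "S01", chrom = "chr3", start = 1, end = 1e7, cn = 1,
    cellFraction = 1))
  pr <- simulateArray(gm, tr, spacing = 2e4, noiseSd = 0.05,
                      missingRate = 0, seed = 6)
  # mis-centre the profile as if normalised on a global median that the
  # aneuploid chromosome dragged down
  pr$logR <- pr$logR + 0.2
  segs <- segmentCohort(pr)
  chr3 <- segs[segs$chrom == "chr3", ]
  expect_true(all(chr3$status == "deleted"))
  expect_equal(sum(chr3$mean_logR * chr3$n_probes) / sum(chr3$n_probes),
               log2(1 - 0.35), tolerance = 0.05)
  expect_true(all(segs$status[segs$chrom != "chr3"] == "neutral"))
})

test_that("planted deletion is recovered across seeds", {
  gm <- makeGenome(c(chr1 = 4e7), bandsPerChrom = 4, genesPerChrom = 0,
                   seed = 2)
  covered <- vapply(1:20, function(s) {
    tr <- TruthSet(purity = 0.7, cnEvents = data.frame(
      sample = "S01", chrom = "chr1", start = 1e7, end = 2.5e7, cn = 1,
      cellFraction = 1))
    pr <- simulateArray(gm, tr, spacing = 2e4, noiseSd = 0.05,
                        missingRate = 0, seed = s)
    segs <- segmentCohort(pr)
    del <- segs[segs$status == "deleted", , drop = FALSE]
    if (nrow(del) == 0) return(0)
    ov <- pmin(del$end, 2.5e7) - pmax(del$start, 1e7 - 1)
    sum(pmax(ov, 0)) / 1.5e7
  }, numeric(1))
  expect_true(all(covered > 0.95))
})

test_that("segments round-trip through the SEG-style TSV", {
  segs <- rbind(segRow(start = 0, end = 1e6, mean_logR = -0.6,
                       mean_mirrored_baf = 0.8),
                segRow(start = 1e6, end = 2e6, mean_logR = 0))
  p <- tempfile(fileext = ".tsv")
  writeSegments(segs, p)
  # emitted coordinates are 1-based inclusive
  raw <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(raw$start, c(1, 1e6 + 1))
  back <- readSegments(p)
  expect_equal(back$start, segs$start)
  expect_equal(back$mean_logR, segs$mean_logR)
  expect_equal(back$status, segs$status)
})
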