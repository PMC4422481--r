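# Fisher classification, the staged filter cascade, consequence annotation
# and cohort summaries.

test_that("one-sided Fisher p matches brute-force enumeration", {
  set.seed(11)
  for (i in 1:300) {
    nref <- sample(0:30, 1); nalt <- sample(0:30, 1)
    tref <- sample(0:30, 1); talt <- sample(0:30, 1)
    if (nref + nalt == 0 || tref + talt == 0) next
    expect_lt(abs(somaticFisherP(nref, nalt, tref, talt) -
                    enumFisherUpper(nref, nalt, tref, talt)), 1e-9)
  }
  # frozen example, value from the enumeration oracle
  expect_equal(somaticFisherP(30, 0, 20, 10), 0.0003985066, tolerance = 1e-6)
})

test_that("basic filter applies coverage, VAF and quality thresholds", {
  expect_equal(basicFilter(siteRow(t_ref = 5, t_alt = 4))$label,
               "min_coverage_tumor")
  expect_equal(basicFilter(siteRow(n_ref = 6, n_alt = 0))$label,
               "min_coverage_normal")
  # VAF exactly at the minimum passes (a minimum, not a strict bound)
  expect_true(basicFilter(siteRow(t_ref = 90, t_alt = 10))$pass)
  expect_equal(basicFilter(siteRow(t_ref = 91, t_alt = 9))$label, "min_vaf")
  expect_equal(basicFilter(siteRow(avg_qual = 16.9))$label, "min_avg_qual")
  expect_true(basicFilter(siteRow(avg_qual = 17))$pass)
})

test_that("site classification assigns the four categories", {
  som <- classifySite(siteRow(n_ref = 30, n_alt = 0, t_ref = 20, t_alt = 10))
  expect_equal(som$category, "somatic")
  expect_equal(som$somatic_p, 0.0003985066, tolerance = 1e-6)

  germ <- classifySite(siteRow(n_ref = 15, n_alt = 15, t_ref = 14,
                               t_alt = 16))
  expect_equal(germ$category, "germline")

  loh <- classifySite(siteRow(n_ref = 15, n_alt = 15, t_ref = 1,
                              t_alt = 29))
  expect_equal(loh$category, "loh")
  # LOH is two-directional: losing the alt allele also qualifies
  loh2 <- classifySite(siteRow(n_ref = 15, n_alt = 15, t_ref = 28,
                               t_alt = 2))
  expect_equal(loh2$category, "loh")

  # reference-like normal but no significant tumor enrichment
  unk <- classifySite(siteRow(n_ref = 28, n_alt = 2, t_ref = 26, t_alt = 4))
  expect_equal(unk$category, "unknown")

  # homozygous germline in both
  hom <- classifySite(siteRow(n_ref = 0, n_alt = 30, t_ref = 1, t_alt = 29))
  expect_equal(hom$category, "germline")

  expect_error(classifySite(siteRow(t_ref = 0, t_alt = 0)), "zero-depth")
})

test_that("somatic indel filter enforces depth, support and germline purity", {
  indel <- function(...) siteRow(is_indel = TRUE, indel_len = -1L, ...)
  expect_equal(filterIndel(indel(t_ref = 40, t_alt = 2))$label,
               "indel_support")
  expect_equal(filterIndel(indel(t_ref = 5, t_alt = 4))$label,
               "indel_coverage")
  # exactly 5% germline frequency passes ("more than 5%" is strict)
  expect_true(filterIndel(indel(n_ref = 19, n_alt = 1))$pass)
  expect_equal(filterIndel(indel(n_ref = 18, n_alt = 2))$label,
               "indel_germline")
  # all-boundary pass: depth 10, support 3, clean germline
  expect_true(filterIndel(indel(t_ref = 7, t_alt = 3, n_ref = 30,
                                n_alt = 0))$pass)
  expect_error(filterIndel(siteRow()), "non-indel")
})

test_that("proximity and cluster flags follow their windows", {
  mk <- function(pos, indel = FALSE) {
    siteRow(pos = pos, is_indel = indel, indel_len = if (indel) -1L else 0L)
  }
  cl <- do.call(rbind, lapply(c(100, 105, 109), mk))
  expect_equal(flagProximityClusters(cl), rep("snv_cluster", 3))
  far <- do.call(rbind, lapply(c(100, 111, 122), mk))
  expect_equal(flagProximityClusters(far), rep("PASS", 3))
  prox <- rbind(mk(200), mk(203, indel = TRUE))
  expect_equal(flagProximityClusters(prox), c("near_indel", "PASS"))
  # 4 bp away: outside the window
  prox2 <- rbind(mk(200), mk(204, indel = TRUE))
  expect_equal(flagProximityClusters(prox2), c("PASS", "PASS"))
})

test_that("somatic quality stage keeps significant, normal-clean calls", {
  sig <- classifiedRow(n_ref = 50, n_alt = 0, t_ref = 30, t_alt = 20)
  expect_true(filterSomaticQuality(sig)$pass)
  dirty <- classifiedRow(n_ref = 47, n_alt = 3, t_ref = 30, t_alt = 20)
  expect_equal(filterSomaticQuality(dirty)$label, "normal_alt")
  weak <- classifiedRow(n_ref = 95, n_alt = 5, t_ref = 85, t_alt = 15)
  weak$somatic_p <- 0.5  # not significant
  expect_equal(filterSomaticQuality(weak)$label, "somatic_p")
  indel <- classifiedRow(n_ref = 49, n_alt = 1, t_ref = 30, t_alt = 20,
                         is_indel = TRUE, indel_len = 2L)
  expect_equal(filterSomaticQuality(indel)$label, "normal_alt")
})

test_that("read-level artifact filter labels the first failing criterion", {
  ok <- classifiedRow()
  expect_true(fpFilter(ok)$pass)
  oneStrand <- classifiedRow(t_ref = 10, t_alt = 40, fwd_alt = 40)
  expect_equal(fpFilter(oneStrand)$label, "fp_strand")
  homop <- classifiedRow(is_indel = TRUE, indel_len = 1L, homopolymer = 8)
  expect_equal(fpFilter(homop)$label, "fp_homopolymer")
  expect_equal(fpFilter(classifiedRow(t_ref = 47, t_alt = 3,
                                      n_ref = 10, n_alt = 10))$label,
               "fp_varcount")
  expect_equal(fpFilter(classifiedRow(read_pos = 0.95))$label, "fp_readpos")
  expect_equal(fpFilter(classifiedRow(dist3p = 0.05))$label, "fp_dist3")
  expect_equal(fpFilter(classifiedRow(mapq_diff = -15))$label, "fp_mapqdiff")
  missing <- classifiedRow()
  missing$read_pos <- NA_real_
  expect_equal(fpFilter(missing)$label, "fp_unscorable")
})

test_that("consequence annotation follows the codon and mod-3 rules", {
  gm <- tinyGenome(nGenes = 5)
  gene <- GenomicRanges::mcols(genes(gm))$gene[1]
  nons <- plantCodingSnv(gm, gene, "nonsense", seed = 1)
  sil <- plantCodingSnv(gm, gene, "silent", seed = 2)
  mis <- plantCodingSnv(gm, gene, "missense", seed = 3)
  snvCalls <- data.frame(chrom = c(nons$chrom, sil$chrom, mis$chrom),
                         pos = c(nons$pos, sil$pos, mis$pos),
                         ref = c(nons$ref, sil$ref, mis$ref),
                         alt = c(nons$alt, sil$alt, mis$alt),
                         is_indel = FALSE, indel_len = 0L)
  ann <- annotateConsequence(snvCalls, gm)
  expect_equal(ann$effect, c("nonsense", "silent", "missense"))
  expect_equal(ann$non_silent, c(TRUE, FALSE, TRUE))
  expect_equal(ann$gene, rep(gene, 3))

  # a 42 bp deletion is divisible by 3: in-frame by arithmetic, even though
  # such events can behave like loss-of-function in practice
  del42 <- plantCodingIndel(gm, gene, len = -42L, seed = 4)
  ins1 <- plantCodingIndel(gm, gene, len = 1L, seed = 5)
  indelCalls <- rbind(
    data.frame(chrom = del42$chrom, pos = del42$pos, ref = del42$ref,
               alt = del42$alt, is_indel = TRUE, indel_len = -42L),
    data.frame(chrom = ins1$chrom, pos = ins1$pos, ref = ins1$ref,
               alt = ins1$alt, is_indel = TRUE, indel_len = 1L))
  annI <- annotateConsequence(indelCalls, gm)
  expect_equal(annI$effect, c("inframe_indel", "frameshift"))
  expect_true(all(annI$non_silent))

  # outside any gene: absent effect, not non-silent
  out <- annotateConsequence(
    data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "T",
               is_indel = FALSE, indel_len = 0L), gm)
  expect_true(is.na(out$effect))
  expect_false(out$non_silent)
})

test_that("mutation rate divides by callable bp with a lower median", {
  mk <- function(sm, n) if (n == 0) NULL else
    data.frame(sample = sm, gene = "G")[rep(1, n), ]
  calls <- rbind(mk("A", 66))
  mr <- mutationRate(calls, 51e6)
  expect_equal(mr$perSample$rate, 66 / 51e6)
  expect_equal(round(mr$perSample$rate * 1e6, 1), 1.3)
  # zero mutations
  mr0 <- mutationRate(calls[0, ], 51e6, samples = "A")
  expect_equal(mr0$perSample$rate, 0)
  # cohort median of {1,2,3}e-6
  cal <- c(A = 1e6, B = 1e6, C = 1e6)
  mr3 <- mutationRate(rbind(mk("A", 1), mk("B", 2), mk("C", 3)), cal)
  expect_equal(mr3$median, 2e-6)
  # even cohort: the lower median
  cal4 <- c(cal, D = 1e6)
  mr4 <- mutationRate(rbind(mk("A", 1), mk("B", 2), mk("C", 3), mk("D", 4)),
                      cal4)
  expect_equal(mr4$median, 2e-6)
  expect_error(mutationRate(calls, 0), "positive")
})

test_that("recurrent genes count distinct mutated samples", {
  calls <- data.frame(
    sample = c("S1", "S2", "S3", "S4", "S4", "S5"),
    gene = c("TSG1", "TSG1", "TSG1", "OTHER", "OTHER", "SINGLE"),
    chrom = "chr1", pos = 1:6, label = NA_character_)
  rec <- recurrentGenes(calls, minSamples = 2)
  expect_equal(rec$gene, "TSG1")
  expect_equal(rec$n_samples, 3L)
  expect_equal(nrow(recurrentGenes(calls[0, ])), 0L)
})

test_that("cascade conserves sites and respects stage order", {
  gm <- tinyGenome(nGenes = 5)
  for (s in 1:5) {
    ct <- cohortTruth(gm, nPassengers = 3, nGermline = 40, seed = s)
    counts <- simulateCounts(gm, ct$truth, meanDepth = 80,
                             nBackgroundSites = 30, seed = s + 100)
    calls <- runCascade(counts)
    expect_equal(sum(calls$pass) + sum(!calls$pass), nrow(counts))
    expect_true(all(calls$filter[calls$pass] == "PASS"))
    expect_true(all(calls$filter[!calls$pass] != "PASS"))
    stageOf <- c(basic = 1, indel_quality = 2, proximity_cluster = 3,
                 somatic_quality = 4, fp_filter = 5, pass = 6)
    expect_true(all(calls$stage %in% names(stageOf)))
    # a site removed at basic has no classification downstream
    expect_true(all(calls$category[calls$stage == "basic" &
                                     !calls$pass] == "filtered"))
  }
})

test_that("planted germline hets are never called somatic at depth >= 30", {
  gm <- tinyGenome(nGenes = 0)
  for (s in 1:5) {
    set.seed(s)
    tr <- TruthSet(purity = 0.7, variants = do.call(rbind, lapply(1:80,
      function(i) data.frame(sample = "S01", chrom = "chr1",
                             pos = 1e5 * i, ref = "A", alt = "T",
                             origin = "germline_het", targetAf = 0.5))))
    counts <- simulateCounts(gm, tr, meanDepth = 40, seed = s + 50)
    keep <- counts$t_ref + counts$t_alt >= 30 &
      counts$n_ref + counts$n_alt >= 30
    calls <- runCascade(counts[keep, , drop = FALSE])
    expect_false(any(calls$category == "somatic"))
  }
})

test_that("clonal somatic variants are recovered without VAF bias", {
  gm <- tinyGenome(nGenes = 0)
  hits <- 0; total <- 0; afs <- numeric(0)
  for (s in 1:20) {
    tr <- TruthSet(purity = 1, variants = do.call(rbind, lapply(1:10,
      function(i) data.frame(sample = "S01", chrom = "chr1",
                             pos = 3e5 * i, ref = "A", alt = "T",
                             origin = "somatic", targetAf = 0.35))))
    counts <- simulateCounts(gm, tr, meanDepth = 60, seed = s + 300)
    keep <- counts$t_ref + counts$t_alt >= 50
    calls <- runCascade(counts[keep, , drop = FALSE])
    ok <- calls$pass & calls$category == "somatic"
    hits <- hits + sum(ok)
    total <- total + nrow(calls)
    afs <- c(afs, calls$t_vaf[ok])
  }
  expect_gte(hits / total, 0.95)
  # unbiased within binomial error of the planted AF
  se <- sqrt(0.35 * 0.65 / 60) / sqrt(length(afs))
  expect_lt(abs(mean(afs) - 0.35), 4 * se)
})

test_that("calls are written as a readable VCF with cascade labels", {
  gm <- tinyGenome(nGenes = 5)
  ct <- cohortTruth(gm, nPassengers = 2, nGermline = 10, seed = 3)
  counts <- simulateCounts(gm, ct$truth, meanDepth = 100, seed = 4)
  calls <- runCascade(counts)
  one <- calls[calls$sample == calls$sample[1], , drop = FALSE]
  p <- tempfile(fileext = ".vcf")
  writeVariantVcf(one, p)
  vcf <- VariantAnnotation::readVcf(p)
  expect_equal(length(vcf), nrow(one))
  expect_setequal(unique(VariantAnnotation::fixed(vcf)$FILTER),
                  unique(one$filter))
  info <- VariantAnnotation::info(vcf)
  ord <- order(one$chrom, one$pos)
  expect_equal(info$CAT, one$category[ord])
  expect_equal(info$TAD, one$t_alt[ord])
})
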