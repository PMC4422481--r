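# Independent oracles and small fixture builders shared across tests.

# Brute-force upper-tail Fisher p for the 2x2 table [[nref, nalt],
# [tref, talt]]: enumerate every table with the observed margins and sum the
# exact hypergeometric probabilities of tumor alt counts >= the observed one.
enumFisherUpper <- function(nref, nalt, tref, talt) {
  rowT <- tref + talt
  colAlt <- nalt + talt
  N <- nref + nalt + rowT
  xs <- max(0, rowT - (N - colAlt)):min(rowT, colAlt)
  probs <- choose(colAlt, xs) * choose(N - colAlt, rowT - xs) /
    choose(N, rowT)
  sum(probs[xs >= talt])
}

# Exhaustive penalized least-squares segmentation: search all breakpoint
# placements up to maxBreaks and return the minimal cost and its breakpoints
# (positions after which a new segment starts).
exhaustiveSegment <- function(y, penalty, maxBreaks = 3) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  best <- list(cost = Inf, breaks = integer(0))
  for (k in 0:maxBreaks) {
    combos <- if (k == 0) list(integer(0))
              else asplit(utils::combn(n - 1, k), 2)
    for (bk in combos) {
      bounds <- c(0, bk, n)
      cost <- sum(vapply(seq_len(length(bounds) - 1), function(i) {
        sse(bounds[i] + 1, bounds[i + 1])
      }, numeric(1))) + penalty * k
      if (cost < best$cost - 1e-12) best <- list(cost = cost, breaks = bk)
    }
  }
  best
}

# tiny genome shared by unit tests (1 chromosome, deterministic)
tinyGenome <- function(chromLen = 1e7, nGenes = 5, seed = 42) {
  makeGenome(c(chr1 = chromLen), bandsPerChrom = 4, genesPerChrom = nGenes,
             seed = seed)
}

# one fully populated allele-count row with clean quality fields
siteRow <- function(sample = "S01", chrom = "chr1", pos = 1000,
                    ref = "A", alt = "T", t_ref = 30, t_alt = 20,
                    n_ref = 50, n_alt = 0, avg_qual = 32,
                    fwd_alt = NULL, read_pos = 0.5, dist3p = 0.45,
                    mapq_diff = 0, homopolymer = 1, is_indel = FALSE,
                    indel_len = 0L) {
  if (is.null(fwd_alt)) fwd_alt <- floor(t_alt / 2)
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
             alt = alt, t_ref = t_ref, t_alt = t_alt, n_ref = n_ref,
             n_alt = n_alt, avg_qual = avg_qual, fwd_alt = fwd_alt,
             rev_alt = t_alt - fwd_alt, read_pos = read_pos,
             dist3p = dist3p, mapq_diff = mapq_diff,
             homopolymer = homopolymer, is_indel = is_indel,
             indel_len = indel_len)
}

# classified single site (bypasses basicFilter for filter-stage unit tests)
classifiedRow <- function(...) {
  classifySite(siteRow(...))
}

# synthetic segment row (0-based half-open)
segRow <- function(sample = "S01", chrom = "chr1", start = 0, end = 1e6,
                   n_probes = 100, mean_logR = 0, mean_mirrored_baf = 0.5,
                   status = NULL, loh = NULL) {
  df <- data.frame(sample = sample, chrom = chrom, start = start, end = end,
                   n_probes = n_probes, mean_logR = mean_logR,
                   mean_mirrored_baf = mean_mirrored_baf)
  if (is.null(status)) callSegments(df)
  else cbind(df, data.frame(status = status, loh = loh %||% FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
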