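# SNP-array profile simulator: emits per-probe LogR / BAF for each sample as
# a two-channel mixture of normal (diploid) and tumor cells.
#
# For a locus carrying an event of copy number c in a fraction f of tumor
# cells, at purity p, the expected total copy number is
#   T = 2(1-p) + p(f*c + (1-f)*2),          LogR = log2(T/2),
# and for a germline-heterozygous probe the expected B-allele fraction is the
# B copy count over T, with the lost (or gained) allele drawn at random per
# probe since probe phase is unknown.

#' Simulate an array profile for every sample of a truth set
#'
#' @param genome A [GenomeModel-class].
#' @param truth A [TruthSet-class].
#' @param spacing Probe spacing in bp (> 0); probes are laid uniformly on
#'   every chromosome.
#' @param noiseSd Gaussian noise SD on LogR (>= 0), in LogR units.
#' @param bafNoiseSd Gaussian noise SD on BAF (clipped to `[0,1]`); defaults
#'   to half the LogR noise.
#' @param hetFraction Fraction of probes that are germline heterozygous.
#' @param missingRate Per-probe, per-sample probability of a missing LogR
#'   (emitted as NA), exercising the cross-sample probe filter.
#' @param samples Character vector of samples to simulate; defaults to the
#'   samples named in the truth set (or `"S01"` when it names none).
#' @param seed Integer seed. Identical arguments give byte-identical output.
#' @return data.frame with columns `sample`, `probe`, `chrom`, `pos`, `logR`,
#'   `baf`, ordered by (sample, chrom, pos).
#' @examples
#' gm <- makeGenome(c(chr1 = 1e7), bandsPerChrom = 4, genesPerChrom = 0)
#' tr <- TruthSet(purity = 1, cnEvents = data.frame(
#'   sample = "S01", chrom = "chr1", start = 2e6, end = 4e6, cn = 1,
#'   cellFraction = 1))
#' pr <- simulateArray(gm, tr, spacing = 1e5, noiseSd = 0)
#' mean(pr$logR[pr$pos >= 2e6 & pr$pos <= 4e6])  # log2(1/2) = -1
#' @export
simulateArray <- function(genome, truth, spacing = 2e4, noiseSd = 0.05,
                          bafNoiseSd = noiseSd / 2, hetFraction = 0.35,
                          missingRate = 0.001, samples = NULL, seed = 1L) {
  stopifnot(spacing > 0, noiseSd >= 0, bafNoiseSd >= 0)
  ev <- cnEvents(truth)
  chl <- chromLengths(genome)
  if (nrow(ev)) {
    bad <- !(ev$chrom %in% names(chl)) | ev$end > chl[ev$chrom] | ev$start < 1
    if (any(bad)) stop("truth event outside genome bounds")
  }
  if (is.null(samples)) {
    samples <- unique(c(ev$sample, truthVariants(truth)$sample))
    if (length(samples) == 0L) samples <- "S01"
    samples <- sort(samples)
  }
  p <- purity(truth)
  set.seed(as.integer(seed))

  # common probe grid
  grid <- do.call(rbind, lapply(names(chl), function(chrom) {
    pos <- seq(spacing, chl[[chrom]], by = spacing)
    data.frame(chrom = chrom, pos = pos)
  }))
  nP <- nrow(grid)
  grid$probe <- sprintf("P%06d", seq_len(nP))

  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    sm <- samples[si]
    cn <- rep(2, nP); cf <- rep(1, nP)
    evs <- ev[ev$sample == sm, , drop = FALSE]
    for (k in seq_len(nrow(evs))) {
      hit <- grid$chrom == evs$chrom[k] & grid$pos >= evs$start[k] &
        grid$pos <= evs$end[k]
      cn[hit] <- evs$cn[k]
      cf[hit] <- evs$cellFraction[k]
    }
    tot <- 2 * (1 - p) + p * (cf * cn + (1 - cf) * 2)
    # germline genotype per probe (per sample: individuals differ)
    gB <- sample(0:2, nP, replace = TRUE,
                 prob = c((1 - hetFraction) / 2, hetFraction,
                          (1 - hetFraction) / 2))
    # B copies among the c event copies; the affected allele is random
    bC <- numeric(nP)
    het <- gB == 1L
    bC[gB == 2L] <- cn[gB == 2L]
    u <- stats::runif(nP) < 0.5  # which haplotype the event hits
    bC[het] <- ifelse(cn[het] <= 1L, ifelse(u[het], cn[het], 0L),
                      ifelse(cn[het] == 2L, 1L, ifelse(u[het], 2L, 1L)))
    bTot <- gB * (1 - p) + p * (cf * bC + (1 - cf) * gB)
    baf <- ifelse(tot > 0, bTot / tot, NA_real_)
    logR <- ifelse(tot > 0, log2(tot / 2), -5)
    if (noiseSd > 0) logR <- logR + stats::rnorm(nP, 0, noiseSd)
    if (bafNoiseSd > 0) {
      baf <- pmin(1, pmax(0, baf + stats::rnorm(nP, 0, bafNoiseSd)))
    }
    if (missingRate > 0) {
      logR[stats::runif(nP) < missingRate] <- NA_real_
    }
    out[[si]] <- data.frame(sample = sm, probe = grid$probe,
                            chrom = grid$chrom, pos = grid$pos,
                            logR = logR, baf = baf)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read probe tables as TSV
#' @param probes Probe data.frame as returned by [simulateArray()].
#' @param path TSV path.
#' @export
writeProbes <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeProbes
#' @export
readProbes <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(sample = "character", probe = "character",
                                   chrom = "character", pos = "numeric",
                                   logR = "numeric", baf = "numeric"))
}
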