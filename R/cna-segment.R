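# Copy-number analysis from probe-level LogR/BAF: cross-sample probe
# filtering, BAF-guided recentring, exact penalized least-squares
# segmentation, and threshold-based gain/loss/LOH calling.
#
# Coordinates are 0-based half-open in memory (BED-compatible) and 1-based
# inclusive in emitted tables.

#' Drop probes with a missing value in any sample
#'
#' A probe is retained only if its LogR is non-missing in every sample;
#' probe order is preserved.
#'
#' @param probes Probe data.frame across samples (see [simulateArray()]).
#' @return Filtered probe data.frame.
#' @export
filterProbes <- function(probes) {
  stopifnot(length(unique(probes$sample)) >= 1L)
  bad <- unique(probes$probe[is.na(probes$logR)])
  out <- probes[!(probes$probe %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# heterozygous-informative mirrored BAF (NA outside the informative band)
mirroredBaf <- function(baf, band = c(0.15, 0.85)) {
  ifelse(!is.na(baf) & baf > band[1] & baf < band[2],
         pmax(baf, 1 - baf), NA_real_)
}

#' Median-center LogR using allelically balanced chromosomes
#'
#' Whole-chromosome events can be masked when profiles are centred on the
#' global median (the event itself drags the median). Here the per-sample
#' centring constant is the median LogR over chromosomes whose
#' heterozygous-informative mirrored BAF shows no allelic imbalance, so an
#' aneuploid chromosome cannot normalise itself away.
#'
#' @param probes Probe data.frame.
#' @param lohThreshold Mirrored-BAF level above which a chromosome is
#'   considered allelically imbalanced and excluded from centring.
#' @param hetBand Informative BAF band.
#' @return Probe data.frame with recentred `logR`.
#' @export
normalizeLogR <- function(probes, lohThreshold = 0.55,
                          hetBand = c(0.15, 0.85)) {
  out <- probes
  for (sm in unique(probes$sample)) {
    i <- probes$sample == sm
    mb <- mirroredBaf(probes$baf[i], hetBand)
    chromImb <- tapply(mb, probes$chrom[i],
                       function(x) mean(x, na.rm = TRUE))
    balanced <- names(chromImb)[!is.na(chromImb) & chromImb <= lohThreshold]
    use <- if (length(balanced)) i & probes$chrom %in% balanced else i
    out$logR[i] <- probes$logR[i] - stats::median(probes$logR[use],
                                                  na.rm = TRUE)
  }
  out
}

# Exact DP for penalized least squares on one numeric series: minimises
# sum of squared deviations from segment means + penalty * (#breakpoints).
# Ties resolve to the earlier segment start, deterministically.
segmentSeries <- function(y, penalty) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  best <- numeric(n + 1L)  # best[j+1] = optimal cost of y[1..j]
  prev <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(j)                       # candidate segment starts
    s <- cs[j + 1L] - cs[i]
    s2 <- cs2[j + 1L] - cs2[i]
    cost <- s2 - s^2 / (j - i + 1L)
    tot <- best[i] + cost + penalty * (i != 1L)
    k <- which.min(tot)
    best[j + 1L] <- tot[k]
    prev[j] <- k - 1L
  }
  ends <- integer(0)
  j <- n
  while (j > 0L) { ends <- c(j, ends); j <- prev[j] }
  starts <- c(1L, ends[-length(ends)] + 1L)
  cbind(start = starts, end = ends)
}

#' Segment one sample's LogR profile
#'
#' Per chromosome, partitions the probe sequence into contiguous segments by
#' exactly minimising the penalized least-squares objective
#' (sum of squared LogR deviations from segment means plus
#' `penalty` x number of breakpoints) with an \eqn{O(n^2)} dynamic program.
#' The default penalty follows a Bayesian-style rule
#' `gamma * sd^2 * log(n)` with the noise SD estimated robustly from
#' first differences.
#'
#' @param probes Probe data.frame for a single sample, sorted by
#'   (chrom, pos); rows with missing LogR must be filtered first.
#' @param penalty Positive breakpoint penalty; `NULL` uses the default rule.
#' @param gamma Multiplier of the default penalty rule.
#' @return Segment data.frame: `sample`, `chrom`, `start`, `end` (0-based
#'   half-open), `n_probes`, `mean_logR`, `mean_mirrored_baf` (NA when no
#'   heterozygous-informative probe falls in the segment).
#' @export
segmentProfile <- function(probes, penalty = NULL, gamma = 40) {
  stopifnot(length(unique(probes$sample)) == 1L)
  ord <- order(probes$chrom, probes$pos)
  if (any(ord != seq_len(nrow(probes)))) {
    stop("probes must be sorted by (chrom, pos)")
  }
  if (!is.null(penalty) && penalty <= 0) stop("penalty must be positive")
  out <- list()
  for (chrom in unique(probes$chrom)) {
    pr <- probes[probes$chrom == chrom, , drop = FALSE]
    y <- pr$logR
    n <- length(y)
    pen <- penalty
    if (is.null(pen)) {
      sdHat <- stats::mad(diff(y)) / sqrt(2)
      pen <- gamma * sdHat^2 * log(n)
      if (!is.finite(pen) || pen <= 0) pen <- 1e-6
    }
    segIdx <- segmentSeries(y, pen)
    pos <- pr$pos
    # physical bounds: probed span, cut at inter-probe midpoints
    bounds <- c(pos[1] - 1,
                if (nrow(segIdx) > 1)
                  floor((pos[segIdx[-nrow(segIdx), "end"]] +
                         pos[segIdx[-1, "start"]]) / 2),
                pos[n])
    mb <- mirroredBaf(pr$baf)
    out[[chrom]] <- data.frame(
      sample = pr$sample[1], chrom = chrom,
      start = bounds[-length(bounds)], end = bounds[-1],
      n_probes = segIdx[, "end"] - segIdx[, "start"] + 1L,
      mean_logR = vapply(seq_len(nrow(segIdx)), function(k) {
        mean(y[segIdx[k, "start"]:segIdx[k, "end"]])
      }, numeric(1)),
      mean_mirrored_baf = vapply(seq_len(nrow(segIdx)), function(k) {
        v <- mb[segIdx[k, "start"]:segIdx[k, "end"]]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Segment every sample of a cohort probe table
#'
#' Applies [filterProbes()], [normalizeLogR()] and [segmentProfile()] per
#' sample, then [callSegments()].
#'
#' @inheritParams segmentProfile
#' @param probes Probe data.frame across samples.
#' @param normalize Recenter LogR before segmentation (default TRUE).
#' @param ... Passed to [callSegments()].
#' @return Called segment data.frame across samples.
#' @export
segmentCohort <- function(probes, penalty = NULL, gamma = 40,
                          normalize = TRUE, ...) {
  probes <- filterProbes(probes)
  if (normalize) probes <- normalizeLogR(probes)
  segs <- do.call(rbind, lapply(sort(unique(probes$sample)), function(sm) {
    pr <- probes[probes$sample == sm, , drop = FALSE]
    pr <- pr[order(pr$chrom, pr$pos), , drop = FALSE]
    segmentProfile(pr, penalty = penalty, gamma = gamma)
  }))
  rownames(segs) <- NULL
  callSegments(segs, ...)
}

#' Call segment status and LOH
#'
#' A segment is amplified when its mean LogR exceeds `gainThreshold`
#' (strictly), deleted when below `lossThreshold` (strictly), otherwise
#' neutral; the LOH flag is set when the mean mirrored BAF strictly exceeds
#' `lohThreshold`.
#'
#' @param segments Segment data.frame (see [segmentProfile()]).
#' @param gainThreshold,lossThreshold,lohThreshold Calling thresholds in
#'   LogR / mirrored-BAF units.
#' @return Segment data.frame with `status` and `loh` columns.
#' @export
callSegments <- function(segments, gainThreshold = 0.25,
                         lossThreshold = -0.25, lohThreshold = 0.55) {
  segments$status <- ifelse(segments$mean_logR > gainThreshold, "amplified",
                     ifelse(segments$mean_logR < lossThreshold, "deleted",
                            "neutral"))
  segments$loh <- !is.na(segments$mean_mirrored_baf) &
    segments$mean_mirrored_baf > lohThreshold
  segments
}

#' Write / read segments as a SEG-style TSV (1-based inclusive coordinates)
#' @param segments Segment data.frame (0-based half-open in memory).
#' @param path TSV path.
#' @export
writeSegments <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1  # emit 1-based inclusive
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSegments
#' @export
readSegments <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(sample = "character",
                                        chrom = "character"))
  x$start <- x$start - 1
  x
}
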