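# Cohort-level copy-number summaries: per-sample alteration burden, cytoband
# calls, cross-sample recurrence, and per-gene net LogR / net BAF scores.

segmentsToGRanges <- function(segments) {
  GenomicRanges::GRanges(segments$chrom,
                         IRanges::IRanges(segments$start + 1, segments$end))
}

#' Per-sample alteration burden from large segments
#'
#' Totals the base pairs lost and gained in large segments (strictly longer
#' than `minSize`), with the corresponding segment counts — the per-sample
#' "cumulative bp altered" summary.
#'
#' @param segments Called segment data.frame for one sample.
#' @param minSize Minimum segment size in bp (strict; default 1 Mb).
#' @return One-row data.frame: `sample`, `bp_lost`, `bp_gained`,
#'   `n_lost`, `n_gained`.
#' @export
summarizeSample <- function(segments, minSize = 1e6) {
  stopifnot(length(unique(segments$sample)) <= 1L)
  len <- segments$end - segments$start
  big <- len > minSize
  lost <- big & segments$status == "deleted"
  gained <- big & segments$status == "amplified"
  data.frame(sample = if (nrow(segments)) segments$sample[1] else NA_character_,
             bp_lost = sum(len[lost]),
             bp_gained = sum(len[gained]),
             n_lost = sum(lost),
             n_gained = sum(gained))
}

#' Summarize every sample of a cohort
#' @inheritParams summarizeSample
#' @export
summarizeCohort <- function(segments, minSize = 1e6) {
  do.call(rbind, lapply(sort(unique(segments$sample)), function(sm) {
    summarizeSample(segments[segments$sample == sm, , drop = FALSE], minSize)
  }))
}

# length fraction of each band overlapped by segments of one status (or the
# LOH flag) for one sample
bandFractions <- function(segs, bands, which = c("deleted", "amplified",
                                                 "loh")) {
  which <- match.arg(which)
  keep <- if (which == "loh") segs$loh else segs$status == which
  res <- numeric(length(bands))
  if (any(keep)) {
    gr <- segmentsToGRanges(segs[keep, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(bands, gr)
    if (length(hits)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        bands[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
      res[as.integer(names(agg))] <- agg
    }
  }
  res / GenomicRanges::width(bands)
}

#' Call cytoband status per sample
#'
#' A cytoband is called deleted (resp. amplified) when strictly more than
#' `minFraction` of its physical length lies inside deleted (resp. amplified)
#' segments.
#'
#' @param segments Called segment data.frame (one or more samples).
#' @param cytobands Cytoband `GRanges` with a `band` metadata column (e.g.
#'   `cytobands(genome)`).
#' @param minFraction Strict length-fraction threshold (default 0.75).
#' @return data.frame: `sample`, `band`, `fraction_deleted`,
#'   `fraction_amplified`, `fraction_loh`, `status`.
#' @export
callCytobands <- function(segments, cytobands, minFraction = 0.75) {
  out <- list()
  for (sm in sort(unique(segments$sample))) {
    segs <- segments[segments$sample == sm, , drop = FALSE]
    fd <- bandFractions(segs, cytobands, "deleted")
    fa <- bandFractions(segs, cytobands, "amplified")
    fl <- bandFractions(segs, cytobands, "loh")
    out[[sm]] <- data.frame(
      sample = sm,
      band = GenomicRanges::mcols(cytobands)$band,
      fraction_deleted = fd,
      fraction_amplified = fa,
      fraction_loh = fl,
      status = ifelse(fd > minFraction, "deleted",
               ifelse(fa > minFraction, "amplified", "neutral")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recurrently lost cytobands across samples
#'
#' A sample supports a band when the band is called deleted in that sample or
#' when at least `lohFraction` of the band's length lies in LOH-flagged
#' segments ("strong LOH"). Bands supported by at least `minSamples` samples
#' are returned, sorted by support (decreasing) then band name.
#'
#' @param bandCalls Output of [callCytobands()] across samples.
#' @param minSamples Minimum number of supporting samples (default 3).
#' @param lohFraction Band length fraction required for strong-LOH support.
#' @return data.frame: `band`, `n_samples`, `samples` (comma-separated).
#' @export
recurrentCytobands <- function(bandCalls, minSamples = 3,
                               lohFraction = 0.75) {
  stopifnot(length(unique(bandCalls$sample)) >= 1L)
  support <- bandCalls$status == "deleted" |
    bandCalls$fraction_loh >= lohFraction
  sup <- bandCalls[support, , drop = FALSE]
  if (nrow(sup) == 0L) {
    return(data.frame(band = character(0), n_samples = integer(0),
                      samples = character(0)))
  }
  agg <- stats::aggregate(sample ~ band, data = sup, FUN = function(x) {
    paste(sort(unique(x)), collapse = ",")
  })
  agg$n_samples <- lengths(strsplit(agg$sample, ","))
  agg <- agg[agg$n_samples >= minSamples, , drop = FALSE]
  agg <- agg[order(-agg$n_samples, agg$band), , drop = FALSE]
  res <- data.frame(band = agg$band, n_samples = agg$n_samples,
                    samples = agg$sample)
  rownames(res) <- NULL
  res
}

#' Net LogR / net BAF gene scores across samples
#'
#' For each gene, sums over samples the mean LogR (and the mean mirrored BAF)
#' of the segment containing the gene's midpoint. A sample whose segments do
#' not cover the gene contributes the neutral baseline: 0 LogR and 0.5
#' mirrored BAF; a covering segment with no informative BAF likewise
#' contributes the 0.5 baseline. Genes in the same segment in every sample
#' get identical scores.
#'
#' @param segments Called segment data.frame across samples.
#' @param genes Gene `GRanges` with a `gene` metadata column.
#' @param samples Samples to sum over; defaults to all samples present.
#' @return data.frame: `gene`, `net_logR`, `net_baf`.
#' @export
geneScores <- function(segments, genes, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  known <- unique(segments$chrom)
  gc <- as.character(GenomicRanges::seqnames(genes))
  if (length(genes) && !all(gc %in% known)) {
    stop("gene on unknown chromosome: ",
         paste(unique(gc[!gc %in% known]), collapse = ","))
  }
  mid <- floor((GenomicRanges::start(genes) + GenomicRanges::end(genes)) / 2)
  midGr <- GenomicRanges::GRanges(gc, IRanges::IRanges(mid, mid))
  netLogR <- numeric(length(genes))
  netBaf <- numeric(length(genes))
  for (sm in samples) {
    segs <- segments[segments$sample == sm, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(midGr, segmentsToGRanges(segs),
                                        select = "first")
    lr <- ifelse(is.na(hits), 0, segs$mean_logR[hits])
    mb <- segs$mean_mirrored_baf[ifelse(is.na(hits), 1L, hits)]
    mb <- ifelse(is.na(hits) | is.na(mb), 0.5, mb)
    netLogR <- netLogR + lr
    netBaf <- netBaf + mb
  }
  data.frame(gene = GenomicRanges::mcols(genes)$gene,
             net_logR = netLogR, net_baf = netBaf)
}
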