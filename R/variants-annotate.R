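# Toy consequence annotation on the synthetic gene models, plus cohort
# mutation-rate and recurrence summaries.

#' Annotate variant consequences on the synthetic gene models
#'
#' A codon-table consequence assigner for the synthetic genome: an SNV in a
#' coding interval is translated through the standard genetic code (silent /
#' missense / nonsense); a coding indel is a frameshift exactly when its
#' length is not a multiple of 3, otherwise an in-frame indel. Variants in a
#' gene but outside its coding intervals are silent; variants outside any
#' gene get an NA effect. `non_silent` is TRUE for missense, nonsense,
#' frameshift and in-frame indels.
#'
#' @param calls Call data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `is_indel`, `indel_len`.
#' @param genome A [GenomeModel-class].
#' @return data.frame: `gene`, `effect`, `non_silent` (one row per call).
#' @export
annotateConsequence <- function(calls, genome) {
  g <- genes(genome)
  seqs <- codingSequences(genome)
  gc <- Biostrings::GENETIC_CODE
  n <- nrow(calls)
  gene <- rep(NA_character_, n)
  effect <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(gene = gene, effect = effect, non_silent = logical(0)))
  }
  vgr <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
  hit <- GenomicRanges::findOverlaps(vgr, g, select = "first")
  for (i in seq_len(n)) {
    gi <- hit[i]
    if (is.na(gi)) next
    nm <- GenomicRanges::mcols(g)$gene[gi]
    gene[i] <- nm
    ci <- GenomicRanges::mcols(g)$coding[[gi]]
    inCoding <- any(calls$pos[i] >= IRanges::start(ci) &
                    calls$pos[i] <= IRanges::end(ci))
    if (!inCoding) { effect[i] <- "silent"; next }
    if (isTRUE(calls$is_indel[i])) {
      effect[i] <- if (calls$indel_len[i] %% 3 != 0) "frameshift"
                   else "inframe_indel"
      next
    }
    # CDS offset of the variant position
    k <- which(calls$pos[i] >= IRanges::start(ci) &
               calls$pos[i] <= IRanges::end(ci))[1]
    before <- if (k > 1) sum(IRanges::width(ci)[seq_len(k - 1)]) else 0L
    cdsPos <- before + (calls$pos[i] - IRanges::start(ci)[k]) + 1L
    seq <- as.character(seqs[[nm]])
    ci0 <- ceiling(cdsPos / 3)
    codon <- substr(seq, 3 * ci0 - 2, 3 * ci0)
    within <- cdsPos - 3 * (ci0 - 1)
    if (substr(codon, within, within) != calls$ref[i]) {
      # reference mismatch against the model: unscorable substitution
      effect[i] <- NA_character_
      next
    }
    newCodon <- codon
    substr(newCodon, within, within) <- calls$alt[i]
    refAa <- gc[[codon]]; altAa <- gc[[newCodon]]
    effect[i] <- if (altAa == "*") "nonsense"
                 else if (altAa == refAa) "silent" else "missense"
  }
  data.frame(gene = gene, effect = effect,
             non_silent = !is.na(effect) & effect != "silent")
}

#' Somatic mutation rate per sample and cohort median
#'
#' The per-sample rate is the passed somatic mutation count divided by the
#' callable territory in bp; the cohort value is the lower median (for an
#' even number of samples, the smaller middle value).
#'
#' @param calls Passed somatic call data.frame with a `sample` column.
#' @param callableBp Callable bp: a single number, or a named vector by
#'   sample.
#' @param samples Samples to report (defaults to those present in `calls`).
#' @return list with `perSample` (data.frame `sample`, `n`, `rate`) and
#'   `median` (per-bp rate).
#' @export
mutationRate <- function(calls, callableBp, samples = NULL) {
  if (any(callableBp <= 0)) stop("callableBp must be positive")
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  n <- vapply(samples, function(sm) sum(calls$sample == sm), numeric(1))
  cb <- if (length(callableBp) == 1L) {
    rep(callableBp, length(samples))
  } else {
    unname(callableBp[samples])
  }
  rate <- n / cb
  list(perSample = data.frame(sample = samples, n = unname(n), rate = rate),
       median = lowerMedian(rate))
}

#' Recurrently mutated genes across samples
#'
#' Counts, per gene, the number of distinct samples carrying at least one
#' non-silent passed mutation in it (multiplicity within a sample does not
#' count), and reports genes reaching `minSamples`, sorted by count then
#' gene name.
#'
#' @param calls Non-silent passed call data.frame with `sample` and `gene`
#'   columns.
#' @param minSamples Minimum number of mutated samples (default 2).
#' @return data.frame: `gene`, `n_samples`, `samples` (comma-separated),
#'   `mutations` (per-sample labels where available).
#' @export
recurrentGenes <- function(calls, minSamples = 2) {
  if (is.null(calls$label)) calls$label <- NA_character_
  calls <- calls[!is.na(calls$gene), , drop = FALSE]
  if (nrow(calls) == 0L) {
    return(data.frame(gene = character(0), n_samples = integer(0),
                      samples = character(0), mutations = character(0)))
  }
  key <- unique(calls[, c("gene", "sample")])
  cnt <- table(key$gene)
  keep <- names(cnt)[cnt >= minSamples]
  if (length(keep) == 0L) {
    return(data.frame(gene = character(0), n_samples = integer(0),
                      samples = character(0), mutations = character(0)))
  }
  res <- do.call(rbind, lapply(keep, function(gn) {
    sub <- calls[calls$gene == gn, , drop = FALSE]
    sms <- sort(unique(sub$sample))
    muts <- vapply(sms, function(sm) {
      lab <- sub$label[sub$sample == sm]
      lab <- lab[!is.na(lab)]
      if (length(lab) == 0L) lab <- paste0(sub$chrom[sub$sample == sm][1],
                                           ":", sub$pos[sub$sample == sm][1])
      paste(unique(lab), collapse = "|")
    }, character(1))
    data.frame(gene = gn, n_samples = length(sms),
               samples = paste(sms, collapse = ","),
               mutations = paste(muts, collapse = ","))
  }))
  res <- res[order(-res$n_samples, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
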