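# Paired tumor-normal allele-count simulator: emits one distilled pileup
# record per site with the quality summaries the false-positive filter
# consumes. Somatic alt fractions are the target fraction in pure tumor
# diluted by purity; germline-het sites inside copy-number events take their
# tumor fraction from the same cellular mixture the array simulator uses, so
# allelic-imbalance (LOH) classification is exercisable.

# tumor-cell mixture allele fraction for a germline-het site under an event
hetTumorAf <- function(p, cn, cellFraction, variantOnAffected) {
  tot <- 2 * (1 - p) + p * (cellFraction * cn + (1 - cellFraction) * 2)
  bC <- if (cn <= 1) (if (variantOnAffected) cn else 0)
        else if (cn == 2) 1 else (if (variantOnAffected) 2 else 1)
  b <- (1 - p) + p * (cellFraction * bC + (1 - cellFraction))
  if (tot > 0) b / tot else NA_real_
}

#' Simulate paired tumor-normal allele counts for every sample of a truth set
#'
#' @inheritParams simulateArray
#' @param meanDepth Mean sequencing depth (> 0); per-site depths are Poisson.
#' @param errorRate Per-base substitution error rate (default 1e-3); drives
#'   alt reads at non-variant sites and normal-sample alt reads at somatic
#'   sites. Set to 0 for a noise-free table.
#' @param nBackgroundSites Number of extra non-variant sites per sample
#'   (uniform over the genome) whose alt reads come only from sequencing
#'   error; used to measure false-call rates.
#' @param meanQual,qualSd Mean/SD of the per-site average base quality of
#'   variant-supporting reads (phred).
#' @return data.frame with one row per (sample, site): `sample`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `t_ref`, `t_alt`, `n_ref`, `n_alt`,
#'   `avg_qual`, `fwd_alt`, `rev_alt`, `read_pos`, `dist3p` (fractions of
#'   read length), `mapq_diff`, `homopolymer` (bp), `is_indel`, `indel_len`.
#' @export
simulateCounts <- function(genome, truth, meanDepth = 100, errorRate = 1e-3,
                           nBackgroundSites = 0, meanQual = 32, qualSd = 3,
                           samples = NULL, seed = 1L) {
  stopifnot(meanDepth > 0, errorRate >= 0)
  chl <- chromLengths(genome)
  vars <- truthVariants(truth)
  if (nrow(vars)) {
    bad <- !(vars$chrom %in% names(chl)) | vars$pos > chl[vars$chrom] |
      vars$pos < 1
    if (any(bad)) stop("variant position outside genome")
  }
  ev <- cnEvents(truth)
  p <- purity(truth)
  if (is.null(samples)) {
    samples <- unique(c(ev$sample, vars$sample))
    if (length(samples) == 0L) samples <- "S01"
    samples <- sort(samples)
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")

  out <- list()
  for (sm in samples) {
    v <- vars[vars$sample == sm, , drop = FALSE]
    if (nBackgroundSites > 0) {
      chrom <- sample(names(chl), nBackgroundSites, replace = TRUE,
                      prob = chl / sum(chl))
      ref <- sample(bases, nBackgroundSites, replace = TRUE)
      bg <- data.frame(sample = sm, chrom = chrom,
                       pos = floor(stats::runif(nBackgroundSites, 1,
                                                chl[chrom])),
                       ref = ref,
                       alt = vapply(ref, function(r)
                         sample(setdiff(bases, r), 1L), character(1)),
                       origin = "background", targetAf = 0,
                       isIndel = FALSE, indelLen = 0L, detectEff = 1,
                       gene = NA_character_, label = NA_character_)
      v <- rbind(v[, names(bg)], bg)
    }
    n <- nrow(v)
    if (n == 0L) next
    tDepth <- stats::rpois(n, meanDepth)
    nDepth <- stats::rpois(n, meanDepth)

    tAf <- numeric(n); nAf <- numeric(n)
    for (i in seq_len(n)) {
      orig <- v$origin[i]
      if (orig == "germline_hom") {
        tAf[i] <- 1 - errorRate; nAf[i] <- 1 - errorRate
      } else if (orig == "germline_het") {
        nAf[i] <- 0.5
        hit <- ev$sample == sm & ev$chrom == v$chrom[i] &
          ev$start <= v$pos[i] & ev$end >= v$pos[i]
        if (any(hit)) {
          k <- which(hit)[1]
          tAf[i] <- hetTumorAf(p, ev$cn[k], ev$cellFraction[k],
                               variantOnAffected = stats::runif(1) < 0.5)
        } else tAf[i] <- 0.5
      } else if (orig == "somatic") {
        tAf[i] <- min(1, v$targetAf[i] * p)
        nAf[i] <- errorRate
      } else {  # background
        tAf[i] <- errorRate; nAf[i] <- errorRate
      }
    }
    tAlt <- stats::rbinom(n, tDepth, tAf)
    # detection-efficiency thinning of alt reads (aligner-dropout emulation)
    thin <- v$detectEff < 1
    if (any(thin)) {
      tAlt[thin] <- stats::rbinom(sum(thin), tAlt[thin], v$detectEff[thin])
    }
    nAlt <- stats::rbinom(n, nDepth, nAf)
    res <- data.frame(
      sample = sm, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      t_ref = tDepth - tAlt, t_alt = tAlt,
      n_ref = nDepth - nAlt, n_alt = nAlt,
      avg_qual = round(pmin(41, pmax(2, stats::rnorm(n, meanQual, qualSd))),
                       1),
      fwd_alt = stats::rbinom(n, tAlt, 0.5),
      read_pos = round(pmin(1, pmax(0, stats::rnorm(n, 0.5, 0.08))), 3),
      dist3p = round(pmin(1, pmax(0, stats::rnorm(n, 0.45, 0.08))), 3),
      mapq_diff = round(stats::rnorm(n, 0, 2), 1),
      homopolymer = sample(1:4, n, replace = TRUE,
                           prob = c(0.7, 0.2, 0.07, 0.03)),
      is_indel = v$isIndel, indel_len = v$indelLen)
    res$rev_alt <- res$t_alt - res$fwd_alt
    out[[sm]] <- res[, c("sample", "chrom", "pos", "ref", "alt",
                         "t_ref", "t_alt", "n_ref", "n_alt", "avg_qual",
                         "fwd_alt", "rev_alt", "read_pos", "dist3p",
                         "mapq_diff", "homopolymer", "is_indel",
                         "indel_len")]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(emptyCounts())
  res <- res[order(res$sample, res$chrom, res$pos), ]
  rownames(res) <- NULL
  res
}

emptyCounts <- function() {
  data.frame(sample = character(0), chrom = character(0), pos = numeric(0),
             ref = character(0), alt = character(0), t_ref = integer(0),
             t_alt = integer(0), n_ref = integer(0), n_alt = integer(0),
             avg_qual = numeric(0), fwd_alt = integer(0), rev_alt = integer(0),
             read_pos = numeric(0), dist3p = numeric(0),
             mapq_diff = numeric(0), homopolymer = integer(0),
             is_indel = logical(0), indel_len = integer(0))
}

#' Write / read allele-count tables as TSV
#' @param counts data.frame as returned by [simulateCounts()].
#' @param path TSV path.
#' @export
writeCounts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(sample = "character",
                                        chrom = "character",
                                        ref = "character",
                                        alt = "character"))
  x
}
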