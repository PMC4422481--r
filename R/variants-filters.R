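# Staged post-classification filter cascade. Stages run in a fixed order and
# a site removed at one stage is not re-tested downstream, so every input
# site ends as exactly one of retained / removed(label).

#' Low-quality somatic indel filter (stage 1)
#'
#' A somatic indel is removed when tumor depth is below `minDepth`, when
#' fewer than `minSupport` reads support it, or when its allele fraction in
#' the germline strictly exceeds `maxGermlineFreq`.
#'
#' @param calls Classified call data.frame rows with `is_indel = TRUE`.
#' @param minDepth Minimum tumor depth (reads).
#' @param minSupport Minimum supporting (alt) reads.
#' @param maxGermlineFreq Maximum germline allele fraction (strict).
#' @return data.frame with `pass` and `label`.
#' @export
filterIndel <- function(calls, minDepth = 10, minSupport = 3,
                        maxGermlineFreq = 0.05) {
  if (any(!calls$is_indel)) stop("filterIndel() called on a non-indel site")
  nVaf <- ifelse(calls$n_ref + calls$n_alt > 0,
                 calls$n_alt / (calls$n_ref + calls$n_alt), 0)
  label <- rep("PASS", nrow(calls))
  label[nVaf > maxGermlineFreq] <- "indel_germline"
  label[calls$t_alt < minSupport] <- "indel_support"
  label[calls$t_ref + calls$t_alt < minDepth] <- "indel_coverage"
  data.frame(pass = label == "PASS", label = label)
}

#' Indel-proximity and SNV-cluster flags (stages 2a / 2b)
#'
#' Within one sample, flags an SNV lying within `indelWindow` bp of any
#' retained indel on the same chromosome, and every SNV belonging to a run of
#' at least `clusterK` SNVs spanning at most `clusterWindow` bp. Flags are
#' labels; the cascade decides removal.
#'
#' @param calls Classified call data.frame for one sample, sorted by
#'   position within chromosome.
#' @param indelWindow Distance to an indel (bp, inclusive).
#' @param clusterK Minimum SNVs forming a cluster.
#' @param clusterWindow Maximum span of a cluster (bp).
#' @return Character vector of labels (`"PASS"`, `"near_indel"`,
#'   `"snv_cluster"`), one per input row; indel rows are always `"PASS"`.
#' @export
flagProximityClusters <- function(calls, indelWindow = 3, clusterK = 3,
                                  clusterWindow = 10) {
  n <- nrow(calls)
  label <- rep("PASS", n)
  for (chrom in unique(calls$chrom)) {
    ci <- which(calls$chrom == chrom)
    pos <- calls$pos[ci]
    if (is.unsorted(pos)) stop("calls must be sorted by position")
    snv <- !calls$is_indel[ci]
    indelPos <- pos[!snv]
    if (length(indelPos)) {
      near <- vapply(pos, function(x) any(abs(x - indelPos) <= indelWindow),
                     logical(1)) & snv
      label[ci[near]] <- "near_indel"
    }
    sp <- pos[snv]
    if (length(sp) >= clusterK) {
      flag <- logical(length(sp))
      for (j in seq_len(length(sp) - clusterK + 1)) {
        if (sp[j + clusterK - 1] - sp[j] <= clusterWindow) {
          flag[j:(j + clusterK - 1)] <- TRUE
        }
      }
      label[ci[snv][flag]] <- "snv_cluster"
    }
  }
  label
}

#' Low-quality somatic variant filter (stage 3)
#'
#' A somatic call is retained only when its Fisher p is significant
#' (below `alpha`), and the normal carries at most `maxNormalVaf` alternate
#' allele for SNVs, or no alternate reads at all for indels.
#'
#' @param calls Classified call data.frame rows with `category == "somatic"`,
#'   carrying `somatic_p` and `n_vaf`.
#' @param alpha Significance level consistent with classification.
#' @param maxNormalVaf Maximum normal alt fraction for SNVs (strict fail
#'   above).
#' @return data.frame with `pass` and `label`.
#' @export
filterSomaticQuality <- function(calls, alpha = 0.05, maxNormalVaf = 0.05) {
  label <- rep("PASS", nrow(calls))
  label[!calls$is_indel & calls$n_vaf > maxNormalVaf] <- "normal_alt"
  label[calls$is_indel & calls$n_alt > 0] <- "normal_alt"
  label[calls$somatic_p >= alpha] <- "somatic_p"
  data.frame(pass = label == "PASS", label = label)
}

#' Default thresholds for the false-positive (read-level artifact) filter
#'
#' All thresholds are configurable; each maps to one named criterion of the
#' read-level artifact filter. The read-length / mismatch-quality-sum delta
#' test is a single optional quality-delta criterion, off by default.
#'
#' @param minVarReads Minimum variant-supporting reads.
#' @param minVarFreq Minimum variant allele fraction.
#' @param readPosRange Allowed range of the mean relative read position.
#' @param minDist3p Minimum mean relative distance to the 3' end.
#' @param strandP Two-sided binomial p (against 0.5) below which strand bias
#'   fails; applied only with at least `strandMinReads` variant reads.
#' @param strandMinReads See `strandP`.
#' @param maxHomopolymer Fail when the homopolymer run at the site reaches
#'   this length (bp).
#' @param minMapqDiff Fail when the variant-minus-reference mapping-quality
#'   difference is below this.
#' @param qualityDelta Optional threshold for the combined quality-delta
#'   test; `NULL` disables it.
#' @return Named list of thresholds.
#' @export
fpConfig <- function(minVarReads = 4, minVarFreq = 0.05,
                     readPosRange = c(0.1, 0.9), minDist3p = 0.1,
                     strandP = 0.01, strandMinReads = 10,
                     maxHomopolymer = 5, minMapqDiff = -10,
                     qualityDelta = NULL) {
  list(minVarReads = minVarReads, minVarFreq = minVarFreq,
       readPosRange = readPosRange, minDist3p = minDist3p,
       strandP = strandP, strandMinReads = strandMinReads,
       maxHomopolymer = maxHomopolymer, minMapqDiff = minMapqDiff,
       qualityDelta = qualityDelta)
}

#' Read-level false-positive filter (stage 4)
#'
#' Applies the artifact criteria in a fixed order — variant reads, variant
#' frequency, read position, distance to 3', strand bias, homopolymer
#' context, mapping-quality difference — and records the first failing
#' criterion. Sites with missing quality fields fail as `"fp_unscorable"`.
#'
#' @param calls Classified call data.frame with populated quality fields
#'   (`t_vaf`, `fwd_alt`, `rev_alt`, `read_pos`, `dist3p`, `mapq_diff`,
#'   `homopolymer`).
#' @param config Threshold list from [fpConfig()].
#' @return data.frame with `pass` and `label`.
#' @export
fpFilter <- function(calls, config = fpConfig()) {
  n <- nrow(calls)
  need <- c("t_vaf", "fwd_alt", "rev_alt", "read_pos", "dist3p",
            "mapq_diff", "homopolymer")
  label <- rep("PASS", n)
  for (i in seq_len(n)) {
    x <- calls[i, ]
    if (any(vapply(need, function(f) is.null(x[[f]]) || is.na(x[[f]]),
                   logical(1)))) {
      label[i] <- "fp_unscorable"; next
    }
    if (x$t_alt < config$minVarReads) { label[i] <- "fp_varcount"; next }
    if (x$t_vaf < config$minVarFreq) { label[i] <- "fp_varfreq"; next }
    if (x$read_pos < config$readPosRange[1] ||
        x$read_pos > config$readPosRange[2]) {
      label[i] <- "fp_readpos"; next
    }
    if (x$dist3p < config$minDist3p) { label[i] <- "fp_dist3"; next }
    nv <- x$fwd_alt + x$rev_alt
    if (nv >= config$strandMinReads) {
      pb <- stats::binom.test(x$fwd_alt, nv, 0.5)$p.value
      if (pb < config$strandP) { label[i] <- "fp_strand"; next }
    }
    if (x$homopolymer >= config$maxHomopolymer) {
      label[i] <- "fp_homopolymer"; next
    }
    if (x$mapq_diff < config$minMapqDiff) { label[i] <- "fp_mapqdiff"; next }
    if (!is.null(config$qualityDelta) &&
        !is.null(x$quality_delta) && !is.na(x$quality_delta) &&
        x$quality_delta < config$qualityDelta) {
      label[i] <- "fp_qualdelta"; next
    }
  }
  data.frame(pass = label == "PASS", label = label)
}

#' Default configuration for the full variant cascade
#' @param minCov,minVaf,minQual Basic filter thresholds (see [basicFilter()]).
#' @param somaticAlpha,hetBand Classification parameters
#'   (see [classifySite()]).
#' @param indelMinDepth,indelMinSupport,indelMaxGermline Stage-1 thresholds.
#' @param indelWindow,clusterK,clusterWindow Stage-2 parameters.
#' @param maxNormalVaf Stage-3 normal contamination bound.
#' @param fp Stage-4 thresholds from [fpConfig()].
#' @return Named list.
#' @export
cascadeConfig <- function(minCov = 10, minVaf = 0.10, minQual = 17,
                          somaticAlpha = 0.05, hetBand = c(0.15, 0.85),
                          indelMinDepth = 10, indelMinSupport = 3,
                          indelMaxGermline = 0.05,
                          indelWindow = 3, clusterK = 3, clusterWindow = 10,
                          maxNormalVaf = 0.05, fp = fpConfig()) {
  list(minCov = minCov, minVaf = minVaf, minQual = minQual,
       somaticAlpha = somaticAlpha, hetBand = hetBand,
       indelMinDepth = indelMinDepth, indelMinSupport = indelMinSupport,
       indelMaxGermline = indelMaxGermline, indelWindow = indelWindow,
       clusterK = clusterK, clusterWindow = clusterWindow,
       maxNormalVaf = maxNormalVaf, fp = fp)
}

#' Run the full classification and filter cascade
#'
#' Order of stages: basic thresholds, classification, (1) somatic indel
#' quality, (2) indel proximity and SNV clustering, (3) somatic variant
#' quality, (4) read-level false-positive filter (applied to germline and
#' somatic calls). A site removed at stage k keeps that stage's label and is
#' not re-tested; the returned table preserves the input rows, so
#' `retained + removed = input` always holds.
#'
#' @param sites Allele-count data.frame across samples.
#' @param config List from [cascadeConfig()].
#' @return data.frame: input columns plus `t_vaf`, `n_vaf`, `somatic_p`,
#'   `category`, `stage` (stage reaching the verdict), `filter` (label or
#'   `"PASS"`), `pass`.
#' @export
runCascade <- function(sites, config = cascadeConfig()) {
  n <- nrow(sites)
  if (n == 0L) {
    out <- cbind(sites, data.frame(t_vaf = numeric(0), n_vaf = numeric(0),
                                   somatic_p = numeric(0),
                                   category = character(0),
                                   stage = character(0),
                                   filter = character(0), pass = logical(0)))
    return(out)
  }
  ord <- order(sites$sample, sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  filter <- rep("PASS", n)
  stage <- rep("basic", n)

  bf <- basicFilter(sites, config$minCov, config$minVaf, config$minQual)
  filter[!bf$pass] <- bf$label[!bf$pass]
  alive <- bf$pass

  cls <- data.frame(t_vaf = rep(NA_real_, n), n_vaf = NA_real_,
                    somatic_p = NA_real_, category = "filtered",
                    stringsAsFactors = FALSE)
  if (any(alive)) {
    cl <- classifySite(sites[alive, , drop = FALSE],
                       somaticAlpha = config$somaticAlpha,
                       hetBand = config$hetBand)
    cls$t_vaf[alive] <- cl$t_vaf
    cls$n_vaf[alive] <- cl$n_vaf
    cls$somatic_p[alive] <- cl$somatic_p
    cls$category[alive] <- cl$category
  }

  # stage 1: somatic indel quality
  s1 <- alive & sites$is_indel & cls$category == "somatic"
  if (any(s1)) {
    f1 <- filterIndel(sites[s1, , drop = FALSE], config$indelMinDepth,
                      config$indelMinSupport, config$indelMaxGermline)
    idx <- which(s1)[!f1$pass]
    filter[idx] <- f1$label[!f1$pass]
    stage[idx] <- "indel_quality"
    alive[idx] <- FALSE
  }

  # stage 2: proximity / clustering per sample (retained sites only)
  for (sm in unique(sites$sample)) {
    s2 <- alive & sites$sample == sm
    if (!any(s2)) next
    lab <- flagProximityClusters(sites[s2, , drop = FALSE],
                                 config$indelWindow, config$clusterK,
                                 config$clusterWindow)
    idx <- which(s2)[lab != "PASS"]
    filter[idx] <- lab[lab != "PASS"]
    stage[idx] <- "proximity_cluster"
    alive[idx] <- FALSE
  }

  # stage 3: somatic variant quality
  s3 <- alive & cls$category == "somatic"
  if (any(s3)) {
    calls3 <- cbind(sites[s3, , drop = FALSE], cls[s3, , drop = FALSE])
    f3 <- filterSomaticQuality(calls3, alpha = config$somaticAlpha,
                               maxNormalVaf = config$maxNormalVaf)
    idx <- which(s3)[!f3$pass]
    filter[idx] <- f3$label[!f3$pass]
    stage[idx] <- "somatic_quality"
    alive[idx] <- FALSE
  }

  # stage 4: read-level artifact filter on germline and somatic calls
  s4 <- alive & cls$category %in% c("germline", "somatic")
  if (any(s4)) {
    calls4 <- cbind(sites[s4, , drop = FALSE], cls[s4, , drop = FALSE])
    f4 <- fpFilter(calls4, config$fp)
    idx <- which(s4)[!f4$pass]
    filter[idx] <- f4$label[!f4$pass]
    stage[idx] <- "fp_filter"
    alive[idx] <- FALSE
  }

  stage[alive] <- "pass"
  out <- cbind(sites, cls,
               data.frame(stage = stage, filter = filter, pass = alive))
  rownames(out) <- NULL
  out
}
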