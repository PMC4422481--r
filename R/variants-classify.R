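# Tumor-normal site classification: VarScan-style basic thresholds, then a
# Fisher-exact comparison of tumor vs normal allele counts that assigns each
# site to germline / somatic / LOH / unknown.

#' One-sided Fisher exact p for tumor alt-allele enrichment
#'
#' Conditional on the margins of the 2x2 table
#' `[[n_ref, n_alt], [t_ref, t_alt]]`, the tumor alt count is hypergeometric;
#' the p-value is the upper tail `P(X >= t_alt)` — the probability of a
#' tumor alt count at least as extreme in the direction of somatic gain.
#'
#' @param n_ref,n_alt,t_ref,t_alt Non-negative read counts (vectorised).
#' @return p-values in `[0, 1]`.
#' @export
somaticFisherP <- function(n_ref, n_alt, t_ref, t_alt) {
  stats::phyper(t_alt - 1, n_alt + t_alt, n_ref + t_ref, t_ref + t_alt,
                lower.tail = FALSE)
}

# two-direction exact p (standard two-sided Fisher) for the LOH comparison
twoSidedFisherP <- function(n_ref, n_alt, t_ref, t_alt) {
  stats::fisher.test(matrix(c(n_ref, n_alt, t_ref, t_alt), nrow = 2,
                            byrow = TRUE))$p.value
}

#' Basic coverage / frequency / quality filter
#'
#' Applies the first-line thresholds: tumor and normal depth at least
#' `minCov` each, tumor variant allele fraction at least `minVaf`, and mean
#' base quality of variant-supporting reads at least `minQual`. The label
#' names the first failing rule.
#'
#' @param sites Allele-count data.frame (see [simulateCounts()]).
#' @param minCov Minimum per-sample depth (reads).
#' @param minVaf Minimum tumor variant allele fraction.
#' @param minQual Minimum mean base quality (phred).
#' @return data.frame with `pass` (logical) and `label` (`"PASS"` or the
#'   first failing rule).
#' @export
basicFilter <- function(sites, minCov = 10, minVaf = 0.10, minQual = 17) {
  tDepth <- sites$t_ref + sites$t_alt
  nDepth <- sites$n_ref + sites$n_alt
  tVaf <- ifelse(tDepth > 0, sites$t_alt / tDepth, 0)
  label <- rep("PASS", nrow(sites))
  label[sites$avg_qual < minQual] <- "min_avg_qual"
  label[tVaf < minVaf] <- "min_vaf"
  label[nDepth < minCov] <- "min_coverage_normal"
  label[tDepth < minCov] <- "min_coverage_tumor"
  data.frame(pass = label == "PASS", label = label)
}

#' Classify paired tumor-normal sites
#'
#' Assigns each site one of four categories from its tumor / normal allele
#' fractions and the Fisher exact comparison of the two count pairs:
#' \itemize{
#'   \item somatic — the normal is reference-like (`n_vaf` below the
#'     heterozygous band) and the one-sided Fisher p for tumor alt
#'     enrichment is below `somaticAlpha`;
#'   \item loh — the normal is heterozygous but the tumor allele fraction
#'     has left the heterozygous band, with a two-direction Fisher p below
#'     `somaticAlpha`;
#'   \item germline — tumor and normal fractions fall in the same genotype
#'     band (both heterozygous, or both homozygous-alt);
#'   \item unknown — anything else.
#' }
#'
#' @param sites Allele-count data.frame; all rows must carry non-zero total
#'   depth in both samples (apply [basicFilter()] first).
#' @param somaticAlpha Significance level for both exact tests.
#' @param hetBand Numeric length-2: the heterozygous allele-fraction band.
#' @return data.frame: the input columns plus `t_vaf`, `n_vaf`, `somatic_p`,
#'   `category`.
#' @export
classifySite <- function(sites, somaticAlpha = 0.05,
                         hetBand = c(0.15, 0.85)) {
  tDepth <- sites$t_ref + sites$t_alt
  nDepth <- sites$n_ref + sites$n_alt
  if (any(tDepth == 0 | nDepth == 0)) {
    stop("zero-depth site: apply basicFilter() before classification")
  }
  tVaf <- sites$t_alt / tDepth
  nVaf <- sites$n_alt / nDepth
  sp <- somaticFisherP(sites$n_ref, sites$n_alt, sites$t_ref, sites$t_alt)

  inHet <- function(v) v >= hetBand[1] & v <= hetBand[2]
  isHom <- function(v) v > hetBand[2]
  category <- rep("unknown", nrow(sites))
  category[inHet(nVaf) & inHet(tVaf)] <- "germline"
  category[isHom(nVaf) & isHom(tVaf)] <- "germline"
  category[nVaf < hetBand[1] & sp < somaticAlpha] <- "somatic"
  lohCand <- which(inHet(nVaf) & !inHet(tVaf) & category != "somatic")
  for (i in lohCand) {
    p2 <- twoSidedFisherP(sites$n_ref[i], sites$n_alt[i],
                          sites$t_ref[i], sites$t_alt[i])
    if (p2 < somaticAlpha) category[i] <- "loh"
  }
  cbind(sites, data.frame(t_vaf = tVaf, n_vaf = nVaf, somatic_p = sp,
                          category = category))
}
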