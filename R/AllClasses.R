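#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   GENETIC_CODE DNA_BASES
NULL

#' Synthetic genome model
#'
#' A scaled-down genome used by the simulator and the annotation steps:
#' a handful of chromosomes, cytobands that tile each chromosome, and toy
#' genes whose coding intervals carry an explicit coding sequence so that
#' variant consequences (silent/missense/nonsense/frameshift) can be
#' computed with a real codon table.
#'
#' @slot chromosomes Named numeric vector of chromosome lengths in bp.
#' @slot cytobands `GRanges` with a `band` metadata column; per chromosome the
#'   bands are sorted, non-overlapping and tile `[0, length)`.
#' @slot genes `GRanges` with metadata columns `gene`, `geneStrand`, and
#'   `coding` (an `IRangesList` of coding intervals inside the gene).
#' @slot codingSeqs `DNAStringSet` named by gene: the concatenated coding
#'   sequence in genomic order (toy convention: read in genomic orientation).
#' @export
setClass("GenomeModel",
  representation(
    chromosomes = "numeric",
    cytobands = "GRanges",
    genes = "GRanges",
    codingSeqs = "DNAStringSet"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  chl <- object@chromosomes
  if (length(chl) == 0L || any(chl <= 0) || is.null(names(chl))) {
    msg <- c(msg, "chromosomes must be a named vector of positive lengths")
  }
  cb <- object@cytobands
  for (chrom in names(chl)) {
    b <- cb[as.character(GenomicRanges::seqnames(cb)) == chrom]
    if (length(b) == 0L) { msg <- c(msg, paste0("no cytobands on ", chrom)); next }
    s <- GenomicRanges::start(b); e <- GenomicRanges::end(b)
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (s[1] != 1L || e[length(e)] != chl[[chrom]] ||
        (length(s) > 1L && any(s[-1] != e[-length(e)] + 1L))) {
      msg <- c(msg, paste0("cytobands do not tile ", chrom))
    }
  }
  g <- object@genes
  if (length(g)) {
    gc <- as.character(GenomicRanges::seqnames(g))
    bad <- !(gc %in% names(chl)) | GenomicRanges::end(g) > chl[gc] |
      GenomicRanges::start(g) < 1L
    if (any(bad)) msg <- c(msg, "gene intervals outside their chromosome")
    cod <- GenomicRanges::mcols(g)$coding
    for (i in seq_along(g)) {
      ci <- cod[[i]]
      if (length(ci) && (min(IRanges::start(ci)) < GenomicRanges::start(g)[i] ||
                         max(IRanges::end(ci)) > GenomicRanges::end(g)[i])) {
        msg <- c(msg, "coding intervals outside their gene")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Planted truth for a synthetic cohort
#'
#' Records everything the simulator plants so downstream stages can be scored
#' against it: tumor purity, copy-number events (with cell fraction, so
#' subclonal events are representable) and variants (germline het/hom or
#' somatic, with a target allelic fraction in the pure tumor).
#'
#' @slot purity Tumor cell fraction in `[0, 1]`, shared across samples.
#' @slot cnEvents data.frame: `sample`, `chrom`, `start`, `end` (1-based
#'   inclusive), `cn` (integer copy number in 0..3), `cellFraction` in (0, 1].
#' @slot variants data.frame: `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `origin` (one of `germline_het`, `germline_hom`, `somatic`), `targetAf`
#'   (allelic fraction in the pure tumor, in (0, 1]), `isIndel`, `indelLen`
#'   (signed bp), `detectEff` (alt-read detection efficiency in (0, 1], models
#'   aligner dropout for long indels), `gene`, `label`.
#' @export
setClass("TruthSet",
  representation(
    purity = "numeric",
    cnEvents = "data.frame",
    variants = "data.frame"
  )
)

setValidity("TruthSet", function(object) {
  msg <- character()
  p <- object@purity
  if (length(p) != 1L || p < 0 || p > 1) msg <- c(msg, "purity must be in [0,1]")
  ev <- object@cnEvents
  if (nrow(ev)) {
    if (any(ev$cellFraction <= 0 | ev$cellFraction > 1)) {
      msg <- c(msg, "cellFraction must be in (0,1]")
    }
    if (any(!ev$cn %in% 0:3)) msg <- c(msg, "cn must be in {0,1,2,3}")
    if (any(ev$end < ev$start | ev$start < 1)) msg <- c(msg, "invalid event bounds")
  }
  v <- object@variants
  if (nrow(v)) {
    if (any(v$targetAf <= 0 | v$targetAf > 1)) {
      msg <- c(msg, "targetAf must be in (0,1]")
    }
    if (any(!v$origin %in% c("germline_het", "germline_hom", "somatic"))) {
      msg <- c(msg, "unknown variant origin")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Integrated per-sample status for a target gene
#'
#' One sample's combined evidence for a gene of interest: which assays were
#' run, any germline loss-of-function variant, any copy-number loss (with its
#' size, or a whole-chromosome / subclonal marker), the somatic mutations with
#' their per-assay allelic fractions, and the derived alteration category.
#'
#' @slot sample Sample identifier.
#' @slot assays Character subset of `c("array", "exome", "targeted")`.
#' @slot germlineVariant Label of a germline loss-of-function variant, or NA.
#' @slot lossSize Loss size in bp (NA when no loss or size not applicable).
#' @slot lossMarker NA, `"segment"`, `"whole_chromosome"` or `"subclonal"`.
#' @slot lossChrom Chromosome of a whole-chromosome loss, or NA.
#' @slot somaticMutations data.frame with columns `label`, `assay`, `af`.
#' @slot subclonal Logical: any evidence points to a subclonal alteration.
#' @slot category One of `mutation_only`, `loss_only`, `both`, `none`.
#' @export
setClass("SampleGeneStatus",
  representation(
    sample = "character",
    assays = "character",
    germlineVariant = "character",
    lossSize = "numeric",
    lossMarker = "character",
    lossChrom = "character",
    somaticMutations = "data.frame",
    subclonal = "logical",
    category = "character"
  )
)

setValidity("SampleGeneStatus", function(object) {
  msg <- character()
  if (!all(object@assays %in% c("array", "exome", "targeted"))) {
    msg <- c(msg, "assays must be a subset of array/exome/targeted")
  }
  if (!object@category %in% c("mutation_only", "loss_only", "both", "none")) {
    msg <- c(msg, "invalid category")
  }
  hasLoss <- !is.na(object@lossMarker)
  hasMut <- nrow(object@somaticMutations) > 0L
  want <- if (hasLoss && hasMut) "both" else if (hasLoss) "loss_only"
          else if (hasMut) "mutation_only" else "none"
  if (object@category != want) msg <- c(msg, "category inconsistent with evidence")
  if (hasLoss && !any(c("array", "exome") %in% object@assays)) {
    msg <- c(msg, "loss evidence requires the array or exome assay")
  }
  af <- object@somaticMutations$af
  if (length(af) && any(!is.na(af) & (af < 0 | af > 1))) {
    msg <- c(msg, "allelic fractions must be in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", length(object@chromosomes), "chromosome(s),",
      length(object@cytobands), "cytoband(s),",
      length(object@genes), "gene(s)\n")
  cat("  total size:", formatMb(sum(object@chromosomes)), "\n")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet: purity", object@purity, "-",
      nrow(object@cnEvents), "copy-number event(s),",
      nrow(object@variants), "variant(s)\n")
})

setMethod("show", "SampleGeneStatus", function(object) {
  cat("SampleGeneStatus", object@sample,
      paste0("[", paste(object@assays, collapse = "+"), "]"),
      "category:", object@category, "\n")
})

#' @describeIn GenomeModel-class Chromosome lengths (named numeric, bp).
#' @param object,x A `GenomeModel`.
#' @export
chromLengths <- function(x) x@chromosomes

#' @describeIn GenomeModel-class Cytoband `GRanges`.
#' @export
cytobands <- function(x) x@cytobands

#' @describeIn GenomeModel-class Gene `GRanges`.
#' @export
genes <- function(x) x@genes

#' @describeIn GenomeModel-class Coding sequences (`DNAStringSet` by gene).
#' @export
codingSequences <- function(x) x@codingSeqs

#' @describeIn TruthSet-class Tumor purity.
#' @export
purity <- function(x) x@purity

#' @describeIn TruthSet-class Planted copy-number events.
#' @export
cnEvents <- function(x) x@cnEvents

#' @describeIn TruthSet-class Planted variants.
#' @export
truthVariants <- function(x) x@variants

#' @describeIn SampleGeneStatus-class Alteration category of a status.
#' @export
statusCategory <- function(x) x@category
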