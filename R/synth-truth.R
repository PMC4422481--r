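#' Construct a truth set
#'
#' @param purity Tumor purity in `[0,1]` shared by all samples; tumors in this
#'   kind of study are selected for high tumor cell content, so the default is
#'   0.7.
#' @param cnEvents data.frame of planted copy-number events (`sample`,
#'   `chrom`, `start`, `end`, `cn`, `cellFraction`); may be empty.
#' @param variants data.frame of planted variants (`sample`, `chrom`, `pos`,
#'   `ref`, `alt`, `origin`, `targetAf`, `isIndel`, `indelLen`, `detectEff`,
#'   `gene`, `label`); may be empty. Missing optional columns are filled.
#' @return A [TruthSet-class].
#' @export
TruthSet <- function(purity = 0.7, cnEvents = NULL, variants = NULL) {
  emptyEv <- data.frame(sample = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        cn = integer(0), cellFraction = numeric(0))
  emptyVar <- data.frame(sample = character(0), chrom = character(0),
                         pos = numeric(0), ref = character(0),
                         alt = character(0), origin = character(0),
                         targetAf = numeric(0), isIndel = logical(0),
                         indelLen = integer(0), detectEff = numeric(0),
                         gene = character(0), label = character(0))
  cnEvents <- cnEvents %||% emptyEv
  variants <- variants %||% emptyVar
  if (nrow(variants)) {
    if (is.null(variants$isIndel)) variants$isIndel <- FALSE
    if (is.null(variants$indelLen)) variants$indelLen <- 0L
    if (is.null(variants$detectEff)) variants$detectEff <- 1
    if (is.null(variants$gene)) variants$gene <- NA_character_
    if (is.null(variants$label)) variants$label <- NA_character_
  } else {
    variants <- emptyVar
  }
  if (nrow(cnEvents) && is.null(cnEvents$cellFraction)) cnEvents$cellFraction <- 1
  methods::new("TruthSet", purity = purity,
               cnEvents = as.data.frame(cnEvents),
               variants = as.data.frame(variants))
}

# Map a CDS offset (1-based within the concatenated coding sequence, genomic
# order) to a genomic position for one gene.
cdsToGenomic <- function(genome, geneName) {
  g <- genes(genome)
  i <- match(geneName, GenomicRanges::mcols(g)$gene)
  if (is.na(i)) stop("unknown gene: ", geneName)
  ci <- GenomicRanges::mcols(g)$coding[[i]]
  pos <- unlist(lapply(seq_along(ci), function(k) {
    seq(IRanges::start(ci)[k], IRanges::end(ci)[k])
  }))
  list(chrom = as.character(GenomicRanges::seqnames(g))[i], positions = pos)
}

#' Plant a coding SNV with a requested consequence
#'
#' Scans the gene's synthetic coding sequence for a single-base substitution
#' producing the requested effect under the standard genetic code and returns
#' a one-row variant data.frame (without sample/origin/AF fields, which the
#' caller supplies).
#'
#' @param genome A [GenomeModel-class].
#' @param gene Gene name in the model.
#' @param effect One of `"nonsense"`, `"missense"`, `"silent"`.
#' @param seed Integer seed controlling which qualifying site is picked.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `gene`, `label`.
#' @export
plantCodingSnv <- function(genome, gene, effect = "nonsense", seed = 1L) {
  effect <- match.arg(effect, c("nonsense", "missense", "silent"))
  set.seed(as.integer(seed))
  seq <- as.character(codingSequences(genome)[[gene]])
  map <- cdsToGenomic(genome, gene)
  nCodon <- nchar(seq) / 3
  gc <- Biostrings::GENETIC_CODE
  for (ci in sample(seq_len(nCodon))) {
    codon <- substr(seq, 3 * ci - 2, 3 * ci)
    refAa <- gc[[codon]]
    for (within in sample(1:3)) {
      refBase <- substr(codon, within, within)
      for (alt in sample(setdiff(c("A", "C", "G", "T"), refBase))) {
        newCodon <- codon
        substr(newCodon, within, within) <- alt
        altAa <- gc[[newCodon]]
        ok <- switch(effect,
          nonsense = altAa == "*",
          silent = altAa == refAa,
          missense = altAa != refAa && altAa != "*")
        if (ok) {
          cdsPos <- 3 * (ci - 1) + within
          lab <- if (effect == "nonsense") paste0(refAa, ci, "*")
                 else paste0(refAa, ci, altAa)
          return(data.frame(chrom = map$chrom,
                            pos = map$positions[cdsPos],
                            ref = refBase, alt = alt,
                            gene = gene, label = lab))
        }
      }
    }
  }
  stop("no substitution with effect '", effect, "' found in ", gene)
}

#' Plant a coding indel
#'
#' Places a small insertion or deletion inside the gene's coding sequence.
#' Deletions take their deleted bases from the synthetic coding sequence;
#' insertions insert random bases. `len > 0` inserts, `len < 0` deletes.
#'
#' @inheritParams plantCodingSnv
#' @param len Signed indel length in bp (non-zero).
#' @param detectEff Alt-read detection efficiency in (0, 1]; values below 1
#'   emulate the loss of supporting reads seen for long indels when reads
#'   fail to align across the event.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `gene`, `label`,
#'   `isIndel`, `indelLen`, `detectEff`.
#' @export
plantCodingIndel <- function(genome, gene, len = -1L, detectEff = 1,
                             seed = 1L) {
  stopifnot(len != 0)
  set.seed(as.integer(seed))
  seq <- as.character(codingSequences(genome)[[gene]])
  map <- cdsToGenomic(genome, gene)
  n <- nchar(seq)
  if (len < 0) {
    cdsPos <- sample.int(n + len - 1L, 1L)  # anchor base before deletion
    ref <- substr(seq, cdsPos, cdsPos - len)
    alt <- substr(seq, cdsPos, cdsPos)
  } else {
    cdsPos <- sample.int(n - 1L, 1L)
    ref <- substr(seq, cdsPos, cdsPos)
    alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = ""))
  }
  aa <- ceiling(cdsPos / 3)
  refAa <- Biostrings::GENETIC_CODE[[substr(seq, 3 * aa - 2, 3 * aa)]]
  lab <- if (abs(len) %% 3 == 0) paste0(refAa, aa, "del")
         else paste0(refAa, aa, "fs")
  data.frame(chrom = map$chrom, pos = map$positions[cdsPos],
             ref = ref, alt = alt, gene = gene, label = lab,
             isIndel = TRUE, indelLen = as.integer(len),
             detectEff = detectEff)
}

# Random germline het SNVs spread over the genome (ref/alt arbitrary bases;
# these sites sit outside the consequence model unless they land in a gene).
randomGermlineVariants <- function(genome, sample, n) {
  chl <- chromLengths(genome)
  chrom <- sample(names(chl), n, replace = TRUE, prob = chl / sum(chl))
  pos <- floor(stats::runif(n, 1, chl[chrom]))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref, alt = alt,
             origin = "germline_het", targetAf = 0.5, isIndel = FALSE,
             indelLen = 0L, detectEff = 1, gene = NA_character_,
             label = NA_character_)
}

#' Planted 12-sample cohort with a recurrently altered tumor-suppressor gene
#'
#' Builds the truth set for the package's reference experiment: a cohort of
#' 12 tumors of purity 0.7 in which one target gene is altered by somatic
#' mutation only (3 samples), copy-number loss only (3 samples, one of them a
#' whole-chromosome loss carried by a sample that also has a germline
#' nonsense variant, one a focal loss), both loss and mutation (2 samples,
#' one with a subclonal loss and a correspondingly low-AF mutation), or not
#' at all (4 samples). Passenger somatic mutations and germline heterozygous
#' variants are added so classification and filtering stages see realistic
#' traffic.
#'
#' @param genome A [GenomeModel-class].
#' @param targetGene Gene name; default picks a gene near the middle of the
#'   last chromosome.
#' @param purity Tumor purity (default 0.7).
#' @param nPassengers Somatic passenger mutations per exome-sequenced sample.
#' @param nGermline Germline heterozygous variants per sample.
#' @param seed Integer seed.
#' @return list with `truth` ([TruthSet-class]), `samples`, `categories`
#'   (named by sample), and `targetGene`.
#' @export
cohortTruth <- function(genome, targetGene = NULL, purity = 0.7,
                        nPassengers = 8, nGermline = 150, seed = 1L) {
  set.seed(deriveSeed(seed, 17L))
  g <- genes(genome)
  chl <- chromLengths(genome)
  lastChrom <- names(chl)[length(chl)]
  if (is.null(targetGene)) {
    onLast <- g[as.character(GenomicRanges::seqnames(g)) == lastChrom]
    if (length(onLast) == 0L) stop("no gene on ", lastChrom)
    mids <- (GenomicRanges::start(onLast) + GenomicRanges::end(onLast)) / 2
    targetGene <- GenomicRanges::mcols(onLast)$gene[
      which.min(abs(mids - chl[[lastChrom]] / 2))]
  }
  ti <- match(targetGene, GenomicRanges::mcols(g)$gene)
  tChrom <- as.character(GenomicRanges::seqnames(g))[ti]
  tMid <- (GenomicRanges::start(g)[ti] + GenomicRanges::end(g)[ti]) / 2

  samples <- sprintf("S%02d", 1:12)
  categories <- stats::setNames(rep("none", 12), samples)
  categories[1:3] <- "mutation_only"
  categories[4:6] <- "loss_only"
  categories[7:8] <- "both"

  focalLoss <- function(sample, sizeBp, cellFraction = 1) {
    s <- max(1, round(tMid - sizeBp / 2))
    e <- min(chl[[tChrom]], s + sizeBp - 1)
    data.frame(sample = sample, chrom = tChrom, start = s, end = e,
               cn = 1L, cellFraction = cellFraction)
  }
  ev <- rbind(
    focalLoss("S04", 15e6),
    data.frame(sample = "S05", chrom = tChrom, start = 1,
               end = chl[[tChrom]], cn = 1L, cellFraction = 1),
    focalLoss("S06", 5e6),
    focalLoss("S07", 15e6),
    focalLoss("S08", 15e6, cellFraction = 0.5),
    # an off-target loss in an unaffected sample, for realism
    data.frame(sample = "S09", chrom = names(chl)[1], start = 1e6,
               end = 9e6, cn = 1L, cellFraction = 1)
  )

  somaticRow <- function(sample, v, targetAf) {
    cbind(data.frame(sample = sample), v,
          data.frame(origin = "somatic", targetAf = targetAf))
  }
  snv <- function(sample, gene, eff, targetAf, sd) {
    v <- plantCodingSnv(genome, gene, eff, seed = deriveSeed(seed, sd))
    v$isIndel <- FALSE; v$indelLen <- 0L; v$detectEff <- 1
    somaticRow(sample, v, targetAf)
  }
  vl <- list(
    snv("S01", targetGene, "nonsense", 0.5, 101L),
    snv("S02", targetGene, "nonsense", 0.5, 102L),
    somaticRow("S03",
               plantCodingIndel(genome, targetGene, len = -1L,
                                seed = deriveSeed(seed, 103L)), 0.5),
    snv("S07", targetGene, "nonsense", 0.5, 107L),
    # subclonal mutation to match the subclonal loss
    snv("S08", targetGene, "nonsense", 0.24, 108L)
  )
  # germline nonsense variant in the whole-chromosome-loss sample
  g5 <- plantCodingSnv(genome, targetGene, "nonsense",
                       seed = deriveSeed(seed, 105L))
  g5$isIndel <- FALSE; g5$indelLen <- 0L; g5$detectEff <- 1
  vl <- c(vl, list(cbind(data.frame(sample = "S05"), g5,
                         data.frame(origin = "germline_het", targetAf = 0.5))))

  # passenger somatic mutations in non-target genes
  otherGenes <- setdiff(GenomicRanges::mcols(g)$gene, targetGene)
  for (k in seq_along(samples)) {
    if (nPassengers > 0 && length(otherGenes)) {
      pg <- sample(otherGenes, min(nPassengers, length(otherGenes)))
      for (j in seq_along(pg)) {
        eff <- sample(c("missense", "silent", "nonsense"), 1,
                      prob = c(0.6, 0.3, 0.1))
        vl <- c(vl, list(snv(samples[k], pg[j], eff, 0.5,
                             sd = 1000L + 20L * k + j)))
      }
    }
    if (nGermline > 0) {
      vl <- c(vl, list(randomGermlineVariants(genome, samples[k], nGermline)))
    }
  }
  vars <- do.call(rbind, vl)
  # a planted site must be unique within a sample
  vars <- vars[!duplicated(vars[, c("sample", "chrom", "pos")]), ]
  list(truth = TruthSet(purity = purity, cnEvents = ev, variants = vars),
       samples = samples, categories = categories, targetGene = targetGene)
}

#' Write / read a truth set as JSON
#' @param truth A [TruthSet-class].
#' @param path JSON file path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(purity = purity(truth),
                            cn_events = cnEvents(truth),
                            variants = truthVariants(truth)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  TruthSet(purity = x$purity,
           cnEvents = if (length(x$cn_events)) as.data.frame(x$cn_events),
           variants = if (length(x$variants)) as.data.frame(x$variants))
}
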