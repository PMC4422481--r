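#' Build a synthetic genome model
#'
#' Constructs a scaled-down stand-in for a real reference annotation: a few
#' chromosomes, cytobands that tile each chromosome exactly, and
#' non-overlapping toy genes whose coding intervals carry a synthetic coding
#' sequence (sense codons only, so a reference codon is never a stop). The
#' output is fully determined by the configuration and seed.
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp
#'   (default three chromosomes of 60/50/40 Mb).
#' @param bandsPerChrom Number of cytobands per chromosome (>= 1).
#' @param genesPerChrom Number of genes per chromosome.
#' @param geneLength Range (min, max) of gene lengths in bp.
#' @param exonsPerGene Range (min, max) of coding intervals per gene.
#' @param seed Integer seed; the same configuration and seed give an
#'   identical model.
#' @return A [GenomeModel-class] object.
#' @examples
#' gm <- makeGenome(c(chr1 = 1e7), bandsPerChrom = 4, genesPerChrom = 5, seed = 1)
#' gm
#' @export
makeGenome <- function(chromLengths = c(chr1 = 6e7, chr2 = 5e7, chr3 = 4e7),
                       bandsPerChrom = 8,
                       genesPerChrom = 30,
                       geneLength = c(2e4, 2e5),
                       exonsPerGene = c(2, 5),
                       seed = 1L) {
  if (length(chromLengths) == 0L || any(chromLengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (is.null(names(chromLengths))) {
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  }
  chromLengths <- round(chromLengths)
  stopifnot(bandsPerChrom >= 1, genesPerChrom >= 0)
  set.seed(as.integer(seed))

  bandList <- list()
  for (chrom in names(chromLengths)) {
    len <- chromLengths[[chrom]]
    k <- min(bandsPerChrom, len)  # cannot have more bands than bp
    cuts <- if (k > 1) sort(sample.int(len - 1L, k - 1L)) else integer(0)
    s <- c(1, cuts + 1)
    e <- c(cuts, len)
    # band names mimic the p/q arm convention
    arm <- ifelse(seq_len(k) <= k / 2, "p", "q")
    idx <- unlist(lapply(split(seq_len(k), arm), function(i) {
      seq_along(i)
    }), use.names = FALSE)
    # p-arm bands count down toward the centromere
    idx[arm == "p"] <- rev(idx[arm == "p"])
    nm <- paste0(sub("^chr", "", chrom), arm, idx)
    bandList[[chrom]] <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                                                band = nm)
  }
  cb <- suppressWarnings(do.call(c, unname(bandList)))

  geneList <- list()
  seqs <- character(0)
  gi <- 0L
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  for (chrom in names(chromLengths)) {
    len <- chromLengths[[chrom]]
    if (genesPerChrom == 0L) next
    # lay genes on a grid with jitter so they never overlap
    slot <- floor(len / genesPerChrom)
    gl <- pmin(round(stats::runif(genesPerChrom, geneLength[1], geneLength[2])),
               max(slot - 2000, 3000))
    gs <- (seq_len(genesPerChrom) - 1L) * slot +
      floor(stats::runif(genesPerChrom, 1, pmax(slot - gl - 1000, 2)))
    ge <- gs + gl - 1
    strand <- sample(c("+", "-"), genesPerChrom, replace = TRUE)
    for (j in seq_len(genesPerChrom)) {
      gi <- gi + 1L
      nm <- sprintf("GENE%03d", gi)
      nEx <- sample(seq(exonsPerGene[1], exonsPerGene[2]), 1L)
      # pick non-overlapping exons inside the gene
      inner <- sort(sample.int(gl[j] - 2L, 2L * nEx)) + gs[j]
      es <- inner[seq(1, 2 * nEx, by = 2)]
      ee <- inner[seq(2, 2 * nEx, by = 2)]
      cds <- sum(ee - es + 1)
      trim <- cds %% 3  # total coding length must be a codon multiple
      if (trim > 0) ee[nEx] <- ee[nEx] - trim
      cds <- cds - trim
      seqs[nm] <- paste(sample(sense, cds / 3, replace = TRUE), collapse = "")
      geneList[[nm]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(gs[j], ge[j]),
        gene = nm, geneStrand = strand[j],
        coding = IRanges::IRangesList(IRanges::IRanges(es, ee))
      )
    }
  }
  gg <- if (length(geneList)) suppressWarnings(do.call(c, unname(geneList)))
        else GenomicRanges::GRanges(gene = character(0),
                                    geneStrand = character(0),
                                    coding = IRanges::IRangesList())
  methods::new("GenomeModel",
               chromosomes = chromLengths,
               cytobands = cb,
               genes = gg,
               codingSeqs = Biostrings::DNAStringSet(seqs))
}

#' Write / read a genome model as plain-text annotation files
#'
#' The model is emitted in standard formats: cytobands and genes as BED
#' (0-based half-open; genes as BED12 with coding intervals as blocks),
#' chromosome sizes as a two-column TSV, coding sequences as FASTA.
#'
#' @param genome A [GenomeModel-class].
#' @param dir Output directory (created if needed).
#' @return `writeGenome` returns `dir` invisibly; `readGenome` the model.
#' @export
writeGenome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chl <- chromLengths(genome)
  utils::write.table(data.frame(chrom = names(chl), length = unname(chl)),
                     file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cb <- cytobands(genome)
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(cb)),
               start = GenomicRanges::start(cb) - 1L,
               end = GenomicRanges::end(cb),
               name = GenomicRanges::mcols(cb)$band),
    file.path(dir, "cytobands.bed"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  g <- genes(genome)
  if (length(g)) {
    cod <- GenomicRanges::mcols(g)$coding
    blocks <- vapply(seq_along(g), function(i) {
      ci <- cod[[i]]
      paste0(paste(IRanges::width(ci), collapse = ","), ",")
    }, character(1))
    starts <- vapply(seq_along(g), function(i) {
      ci <- cod[[i]]
      paste0(paste(IRanges::start(ci) - GenomicRanges::start(g)[i],
                   collapse = ","), ",")
    }, character(1))
    bed12 <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      name = GenomicRanges::mcols(g)$gene,
      score = 0L,
      strand = GenomicRanges::mcols(g)$geneStrand,
      thickStart = GenomicRanges::start(g) - 1L,
      thickEnd = GenomicRanges::end(g),
      rgb = "0",
      blockCount = lengths(cod),
      blockSizes = blocks,
      blockStarts = starts)
  } else {
    bed12 <- data.frame()
  }
  utils::write.table(bed12, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(codingSequences(genome),
                              file.path(dir, "coding.fa"))
  invisible(dir)
}

#' @rdname writeGenome
#' @export
readGenome <- function(dir) {
  sz <- utils::read.table(file.path(dir, "chrom.sizes"), sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chl <- stats::setNames(sz$length, sz$chrom)
  cbd <- utils::read.table(file.path(dir, "cytobands.bed"), sep = "\t",
                           col.names = c("chrom", "start", "end", "name"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  cb <- GenomicRanges::GRanges(cbd$chrom,
                               IRanges::IRanges(cbd$start + 1L, cbd$end),
                               band = cbd$name)
  gfile <- file.path(dir, "genes.bed")
  gbed <- if (file.size(gfile) > 0) {
    utils::read.table(gfile, sep = "\t", colClasses = "character")
  } else data.frame()
  if (nrow(gbed)) {
    geneList <- lapply(seq_len(nrow(gbed)), function(i) {
      gs <- as.integer(gbed[i, 2]) + 1L
      bw <- as.integer(strsplit(gbed[i, 11], ",")[[1]])
      bs <- as.integer(strsplit(gbed[i, 12], ",")[[1]])
      es <- gs + bs
      GenomicRanges::GRanges(gbed[i, 1],
                             IRanges::IRanges(gs, as.integer(gbed[i, 3])),
                             gene = gbed[i, 4], geneStrand = gbed[i, 6],
                             coding = IRanges::IRangesList(
                               IRanges::IRanges(es, es + bw - 1L)))
    })
    gg <- suppressWarnings(do.call(c, geneList))
  } else {
    gg <- GenomicRanges::GRanges(gene = character(0),
                                 geneStrand = character(0),
                                 coding = IRanges::IRangesList())
  }
  methods::new("GenomeModel", chromosomes = chl, cytobands = cb, genes = gg,
               codingSeqs = Biostrings::readDNAStringSet(
                 file.path(dir, "coding.fa")))
}
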