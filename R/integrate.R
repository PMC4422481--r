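# Evidence integration: combine copy-number calls, somatic mutations and
# germline variants for a target gene into one status per sample, summarize
# the cohort, and render / parse the human-readable status table.

#' Assemble the integrated status of one sample for a target gene
#'
#' Combines the sample's called segments (array evidence), its passed
#' somatic mutations in the gene (sequencing evidence) and any germline
#' loss-of-function variant into a [SampleGeneStatus-class]. A copy-number
#' loss is recorded when a deleted segment contains the gene midpoint; it is
#' marked whole-chromosome when the segment covers more than
#' `wholeChromFraction` of that chromosome's probed span, and subclonal when
#' the segment amplitude is less than `subclonalLogRFactor` times the clonal
#' one-copy expectation `|log2(1 - purity/2)|`. A somatic mutation is
#' subclonal when its allelic fraction is below `subclonalAfFactor` times
#' the clonal heterozygous expectation `purity / 2`. Germline variants are
#' recorded but do not by themselves make the sample "altered": the category
#' reflects somatic loss and somatic mutation evidence only.
#'
#' @param sample Sample id.
#' @param assays Character subset of `c("array", "exome", "targeted")`.
#' @param gene Gene location: list or one-row data.frame with `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param segments Called segment data.frame for this sample (array
#'   evidence), or NULL.
#' @param somatic data.frame of passed somatic mutations in the gene:
#'   columns `label`, `assay`, `af` (one row per mutation x assay), or NULL.
#' @param germline Character vector of germline loss-of-function variant
#'   labels in the gene (the first is reported), or NULL.
#' @param purity Assumed tumor purity (default 0.7).
#' @param subclonalAfFactor,subclonalLogRFactor Fractions of the clonal
#'   expectation below which evidence is marked subclonal.
#' @param wholeChromFraction Probed-span fraction above which a loss is a
#'   whole-chromosome event.
#' @return A [SampleGeneStatus-class].
#' @export
assembleStatus <- function(sample, assays, gene, segments = NULL,
                           somatic = NULL, germline = NULL, purity = 0.7,
                           subclonalAfFactor = 0.5,
                           subclonalLogRFactor = 0.5,
                           wholeChromFraction = 0.95) {
  assays <- match.arg(assays, c("array", "exome", "targeted"),
                      several.ok = TRUE)
  if (!is.null(segments) && nrow(segments) > 0 &&
      !any(c("array", "exome") %in% assays)) {
    stop("segment evidence requires the array or exome assay")
  }
  if (!is.null(somatic) && nrow(somatic) > 0) {
    seqAssays <- intersect(c("exome", "targeted"), assays)
    if (length(seqAssays) == 0L) {
      stop("mutation evidence requires a sequencing assay")
    }
    if (!all(somatic$assay %in% assays)) {
      stop("mutation evidence references an undeclared assay")
    }
  }
  if (!is.null(germline) && length(germline) > 0 &&
      !"exome" %in% assays) {
    stop("germline evidence requires the exome assay")
  }

  lossSize <- NA_real_; lossMarker <- NA_character_
  lossChrom <- NA_character_
  subclonal <- FALSE
  if (!is.null(segments) && nrow(segments) > 0) {
    mid <- floor((gene$start + gene$end) / 2)
    hit <- segments$chrom == gene$chrom & segments$status == "deleted" &
      segments$start < mid & segments$end >= mid
    if (any(hit)) {
      seg <- segments[which(hit)[1], ]
      lossSize <- seg$end - seg$start
      onChrom <- segments[segments$chrom == gene$chrom, , drop = FALSE]
      span <- max(onChrom$end) - min(onChrom$start)
      clonalLogR <- abs(log2(1 - purity / 2))
      if (lossSize > wholeChromFraction * span) {
        lossMarker <- "whole_chromosome"
        lossChrom <- gene$chrom
      } else if (abs(seg$mean_logR) < subclonalLogRFactor * clonalLogR) {
        lossMarker <- "subclonal"
        subclonal <- TRUE
      } else {
        lossMarker <- "segment"
      }
    }
  }

  muts <- data.frame(label = character(0), assay = character(0),
                     af = numeric(0))
  if (!is.null(somatic) && nrow(somatic) > 0) {
    muts <- somatic[, c("label", "assay", "af")]
    rownames(muts) <- NULL
    if (any(muts$af < subclonalAfFactor * purity / 2, na.rm = TRUE)) {
      subclonal <- TRUE
    }
  }

  hasLoss <- !is.na(lossMarker)
  hasMut <- nrow(muts) > 0
  category <- if (hasLoss && hasMut) "both" else if (hasLoss) "loss_only"
              else if (hasMut) "mutation_only" else "none"
  methods::new("SampleGeneStatus",
               sample = sample, assays = assays,
               germlineVariant = if (length(germline)) germline[1]
                                 else NA_character_,
               lossSize = lossSize, lossMarker = lossMarker,
               lossChrom = lossChrom, somaticMutations = muts,
               subclonal = subclonal, category = category)
}

#' Summarize a cohort of integrated statuses
#'
#' Counts samples by alteration category; `fraction_altered` is altered over
#' total, also rendered as an integer percentage (truncated, as cohort
#' tables print it).
#'
#' @param statuses List of [SampleGeneStatus-class] objects.
#' @return list: `n_samples`, `n_mutation_only`, `n_loss_only`, `n_both`,
#'   `n_none`, `n_altered`, `fraction_altered`, `percent_altered`.
#' @export
cohortSummary <- function(statuses) {
  if (length(statuses) == 0L) stop("empty status list")
  cat <- vapply(statuses, statusCategory, character(1))
  n <- length(cat)
  nm <- sum(cat == "mutation_only")
  nl <- sum(cat == "loss_only")
  nb <- sum(cat == "both")
  altered <- nm + nl + nb
  list(n_samples = n, n_mutation_only = nm, n_loss_only = nl, n_both = nb,
       n_none = sum(cat == "none"), n_altered = altered,
       fraction_altered = altered / n,
       percent_altered = floor(100 * altered / n))
}

assayLetters <- c(array = "A", exome = "E", targeted = "T")

formatAf <- function(muts, assays) {
  if (nrow(muts) == 0L) return("")
  labs <- unique(muts$label)
  vapply(labs, function(lb) {
    sub <- muts[muts$label == lb, , drop = FALSE]
    if (nrow(sub) == 1L) {
      paste0(lb, " (", round(100 * sub$af), "%)")
    } else {
      paste0(lb, " (", paste0(assayLetters[sub$assay], ":",
                              round(100 * sub$af), "%", collapse = ", "),
             ")")
    }
  }, character(1)) |> paste(collapse = "; ")
}

#' Render integrated statuses as the cohort status table
#'
#' One row per sample with the assay string in A/E/T notation, the germline
#' variant, the loss cell (size in Mb, chromosome marker for a
#' whole-chromosome loss, or `subclonal`), and the somatic mutations with
#' per-assay allelic fractions. `NA` marks evidence a sample was not assayed
#' for; an empty cell means assayed with no finding.
#'
#' @param statuses List of [SampleGeneStatus-class] objects.
#' @return data.frame: `sample`, `assays`, `germline`, `loh`, `somatic`.
#' @export
renderStatusTable <- function(statuses) {
  do.call(rbind, lapply(statuses, function(st) {
    lossAssayed <- any(c("array", "exome") %in% st@assays)
    loh <- if (!lossAssayed) "NA"
           else if (is.na(st@lossMarker)) ""
           else if (st@lossMarker == "whole_chromosome") st@lossChrom
           else if (st@lossMarker == "subclonal") "subclonal"
           else formatMb(st@lossSize)
    germ <- if (!"exome" %in% st@assays) "NA"
            else if (is.na(st@germlineVariant)) "" else st@germlineVariant
    data.frame(sample = st@sample,
               assays = paste(assayLetters[st@assays], collapse = " + "),
               germline = germ, loh = loh,
               somatic = formatAf(st@somaticMutations, st@assays))
  }))
}

#' Read a rendered status table back into statuses
#'
#' Inverse of [renderStatusTable()]: parses the assay string, the loss cell
#' and the per-assay allelic fractions, and re-derives each category from the
#' parsed evidence, so integration is idempotent through its own rendered
#' output.
#'
#' @param x data.frame as produced by [renderStatusTable()], or a TSV path.
#' @param purity,subclonalAfFactor See [assembleStatus()].
#' @return List of [SampleGeneStatus-class] objects.
#' @export
readStatusTable <- function(x, purity = 0.7, subclonalAfFactor = 0.5) {
  if (is.character(x)) {
    x <- utils::read.table(x, sep = "\t", header = TRUE,
                           colClasses = "character",
                           na.strings = character(0))
  }
  x[is.na(x)] <- ""
  lapply(seq_len(nrow(x)), function(i) {
    letters <- trimws(strsplit(x$assays[i], "\\+")[[1]])
    assays <- names(assayLetters)[match(letters, assayLetters)]
    loh <- x$loh[i]
    lossSize <- NA_real_; lossMarker <- NA_character_
    lossChrom <- NA_character_; subclonal <- FALSE
    if (!loh %in% c("", "NA")) {
      if (grepl("Mb$", loh)) {
        lossSize <- as.numeric(sub(" *Mb$", "", loh)) * 1e6
        lossMarker <- "segment"
      } else if (loh == "subclonal") {
        lossMarker <- "subclonal"; subclonal <- TRUE
      } else {
        lossMarker <- "whole_chromosome"; lossChrom <- loh
      }
    }
    muts <- data.frame(label = character(0), assay = character(0),
                       af = numeric(0))
    som <- x$somatic[i]
    if (!som %in% c("", "NA")) {
      for (part in trimws(strsplit(som, ";")[[1]])) {
        m <- regmatches(part, regexec("^(\\S+) \\((.*)\\)$", part))[[1]]
        lab <- m[2]
        for (af in trimws(strsplit(m[3], ",")[[1]])) {
          if (grepl(":", af)) {
            letter <- sub(":.*", "", af)
            assay <- names(assayLetters)[match(letter, assayLetters)]
            pct <- as.numeric(sub("%$", "", sub(".*:", "", af)))
          } else {
            assay <- intersect(c("exome", "targeted"), assays)[1]
            pct <- as.numeric(sub("%$", "", af))
          }
          muts <- rbind(muts, data.frame(label = lab, assay = assay,
                                         af = pct / 100))
        }
      }
      if (any(muts$af < subclonalAfFactor * purity / 2)) subclonal <- TRUE
    }
    germ <- x$germline[i]
    hasLoss <- !is.na(lossMarker)
    hasMut <- nrow(muts) > 0
    category <- if (hasLoss && hasMut) "both" else if (hasLoss) "loss_only"
                else if (hasMut) "mutation_only" else "none"
    methods::new("SampleGeneStatus", sample = x$sample[i], assays = assays,
                 germlineVariant = if (germ %in% c("", "NA")) NA_character_
                                   else germ,
                 lossSize = lossSize, lossMarker = lossMarker,
                 lossChrom = lossChrom, somaticMutations = muts,
                 subclonal = subclonal, category = category)
  })
}

#' The bundled 12-sample reference status table
#'
#' Loads the package's bundled per-sample evidence table for the cohort's
#' most-altered gene (12 tumors assayed by array, exome and/or targeted
#' sequencing) and returns the parsed statuses.
#'
#' @return List of [SampleGeneStatus-class] objects (length 12).
#' @export
referenceStatusTable <- function() {
  readStatusTable(system.file("extdata", "cohort_gene_status.tsv",
                              package = "mesoscape", mustWork = TRUE))
}
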