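# Pipeline orchestration: a validated run configuration, stage functions
# that communicate through files in an output directory, and a driver that
# chains them. Stages log one conservation line per filter step.

#' Build a run configuration
#'
#' All thresholds of every stage with their defaults, plus the simulation
#' parameters. A single `seed` fans out to per-stage child seeds through
#' [deriveSeed()] so stages can be rerun independently.
#'
#' @param seed Master seed.
#' @param purity Simulated tumor purity.
#' @param probeSpacing Array probe spacing (bp).
#' @param noiseSd LogR noise SD.
#' @param meanDepth Mean sequencing depth.
#' @param errorRate Per-base sequencing error rate.
#' @param nPassengers,nGermline Passenger somatic / germline variants per
#'   sample in the simulated cohort.
#' @param segPenalty Segmentation penalty (NA = automatic rule).
#' @param segGamma Automatic penalty multiplier.
#' @param gainThreshold,lossThreshold Segment amplification / deletion
#'   thresholds (LogR).
#' @param lohThreshold Mirrored-BAF LOH threshold.
#' @param bandFraction Cytoband call length fraction (strict).
#' @param minSegSize Minimum segment size for burden summaries (bp).
#' @param minSamplesBand,minSamplesGene Recurrence thresholds.
#' @param cascade Variant-cascade thresholds from [cascadeConfig()].
#' @param subclonalAfFactor,subclonalLogRFactor,wholeChromFraction
#'   Integration parameters (see [assembleStatus()]).
#' @param targetGene Target gene name (NA = chosen by the simulator).
#' @return Named list (a validated run configuration).
#' @export
runConfig <- function(seed = 1L, purity = 0.7, probeSpacing = 2e4,
                      noiseSd = 0.05, meanDepth = 100, errorRate = 1e-3,
                      nPassengers = 8, nGermline = 150,
                      segPenalty = NA_real_, segGamma = 40,
                      gainThreshold = 0.25, lossThreshold = -0.25,
                      lohThreshold = 0.55, bandFraction = 0.75,
                      minSegSize = 1e6, minSamplesBand = 3,
                      minSamplesGene = 2, cascade = cascadeConfig(),
                      subclonalAfFactor = 0.5, subclonalLogRFactor = 0.5,
                      wholeChromFraction = 0.95,
                      targetGene = NA_character_) {
  config <- list(seed = seed, purity = purity, probeSpacing = probeSpacing,
                 noiseSd = noiseSd, meanDepth = meanDepth,
                 errorRate = errorRate, nPassengers = nPassengers,
                 nGermline = nGermline, segPenalty = segPenalty,
                 segGamma = segGamma, gainThreshold = gainThreshold,
                 lossThreshold = lossThreshold, lohThreshold = lohThreshold,
                 bandFraction = bandFraction, minSegSize = minSegSize,
                 minSamplesBand = minSamplesBand,
                 minSamplesGene = minSamplesGene, cascade = cascade,
                 subclonalAfFactor = subclonalAfFactor,
                 subclonalLogRFactor = subclonalLogRFactor,
                 wholeChromFraction = wholeChromFraction,
                 targetGene = targetGene)
  validateRunConfig(config)
  config
}

#' Validate a run configuration
#'
#' Checks types and ranges; errors name the offending field.
#'
#' @param config List as returned by [runConfig()].
#' @return `config`, invisibly, if valid.
#' @export
validateRunConfig <- function(config) {
  needPos <- c("probeSpacing", "meanDepth", "segGamma", "minSegSize",
               "minSamplesBand", "minSamplesGene")
  for (f in needPos) {
    if (!is.numeric(config[[f]]) || config[[f]] <= 0) {
      stop("invalid config field '", f, "': must be positive")
    }
  }
  needNonNeg <- c("noiseSd", "errorRate", "nPassengers", "nGermline")
  for (f in needNonNeg) {
    if (!is.numeric(config[[f]]) || config[[f]] < 0) {
      stop("invalid config field '", f, "': must be non-negative")
    }
  }
  if (!is.na(config$segPenalty) && config$segPenalty <= 0) {
    stop("invalid config field 'segPenalty': must be positive or NA")
  }
  if (config$purity < 0 || config$purity > 1) {
    stop("invalid config field 'purity': must be in [0,1]")
  }
  for (f in c("bandFraction", "wholeChromFraction")) {
    if (config[[f]] <= 0 || config[[f]] > 1) {
      stop("invalid config field '", f, "': must be in (0,1]")
    }
  }
  cc <- config$cascade
  for (f in c("minCov", "minVaf", "minQual", "somaticAlpha",
              "indelMinDepth", "indelMinSupport")) {
    if (!is.numeric(cc[[f]]) || cc[[f]] < 0) {
      stop("invalid config field 'cascade.", f, "': must be non-negative")
    }
  }
  invisible(config)
}

#' Write / read a run configuration as JSON
#' @param config List from [runConfig()].
#' @param path JSON path.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$segPenalty)) x$segPenalty <- NA_real_
  if (is.null(x$targetGene)) x$targetGene <- NA_character_
  if (is.null(x$cascade$fp$qualityDelta)) x$cascade$fp["qualityDelta"] <-
    list(NULL)
  validateRunConfig(x)
  x
}

logLine <- function(outdir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = file.path(outdir, "pipeline.log"), append = TRUE,
      sep = "")
  invisible(msg)
}

stageSimulate <- function(config, outdir) {
  genome <- makeGenome(seed = deriveSeed(config$seed, 1L))
  ct <- cohortTruth(genome,
                    targetGene = if (is.na(config$targetGene)) NULL
                                 else config$targetGene,
                    purity = config$purity,
                    nPassengers = config$nPassengers,
                    nGermline = config$nGermline,
                    seed = deriveSeed(config$seed, 2L))
  probes <- simulateArray(genome, ct$truth, spacing = config$probeSpacing,
                          noiseSd = config$noiseSd,
                          samples = ct$samples,
                          seed = deriveSeed(config$seed, 3L))
  counts <- simulateCounts(genome, ct$truth, meanDepth = config$meanDepth,
                           errorRate = config$errorRate,
                           samples = ct$samples,
                           seed = deriveSeed(config$seed, 4L))
  writeGenome(genome, file.path(outdir, "genome"))
  writeTruth(ct$truth, file.path(outdir, "truth.json"))
  writeProbes(probes, file.path(outdir, "probes.tsv"))
  writeCounts(counts, file.path(outdir, "counts.tsv"))
  jsonlite::write_json(list(targetGene = ct$targetGene,
                            samples = ct$samples,
                            categories = as.list(ct$categories)),
                       file.path(outdir, "meta.json"), auto_unbox = TRUE)
  logLine(outdir, "simulate: ", nrow(probes), " probe rows, ",
          nrow(counts), " count rows, target gene ", ct$targetGene)
}

stageSegment <- function(config, outdir) {
  probes <- readProbes(file.path(outdir, "probes.tsv"))
  kept <- filterProbes(probes)
  logLine(outdir, "segment: probe filter in=", nrow(probes), " retained=",
          nrow(kept), " removed=", nrow(probes) - nrow(kept))
  segs <- segmentCohort(probes,
                        penalty = if (is.na(config$segPenalty)) NULL
                                  else config$segPenalty,
                        gamma = config$segGamma,
                        gainThreshold = config$gainThreshold,
                        lossThreshold = config$lossThreshold,
                        lohThreshold = config$lohThreshold)
  writeSegments(segs, file.path(outdir, "segments.tsv"))
  logLine(outdir, "segment: ", nrow(segs), " segments across ",
          length(unique(segs$sample)), " samples")
}

stageCallCna <- function(config, outdir) {
  segs <- readSegments(file.path(outdir, "segments.tsv"))
  genome <- readGenome(file.path(outdir, "genome"))
  summary <- summarizeCohort(segs, minSize = config$minSegSize)
  utils::write.table(summary, file.path(outdir, "sample_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bands <- callCytobands(segs, cytobands(genome),
                         minFraction = config$bandFraction)
  utils::write.table(bands, file.path(outdir, "band_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- recurrentCytobands(bands, minSamples = config$minSamplesBand,
                            lohFraction = config$bandFraction)
  utils::write.table(rec, file.path(outdir, "recurrent_bands.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gs <- geneScores(segs, genes(genome))
  utils::write.table(gs, file.path(outdir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logLine(outdir, "callcna: ", nrow(rec), " recurrent band(s)")
}

stageCallVar <- function(config, outdir) {
  counts <- readCounts(file.path(outdir, "counts.tsv"))
  genome <- readGenome(file.path(outdir, "genome"))
  calls <- runCascade(counts, config$cascade)
  stageOrder <- c("basic", "indel_quality", "proximity_cluster",
                  "somatic_quality", "fp_filter")
  alive <- nrow(calls)
  for (st in stageOrder) {
    removed <- sum(!calls$pass & calls$stage == st)
    logLine(outdir, "callvar stage ", st, ": in=", alive, " retained=",
            alive - removed, " removed=", removed)
    alive <- alive - removed
  }
  logLine(outdir, "callvar: in=", nrow(calls), " retained=",
          sum(calls$pass), " removed=", sum(!calls$pass),
          " (conservation: ", sum(calls$pass) + sum(!calls$pass), ")")
  ann <- annotateConsequence(calls, genome)
  calls <- cbind(calls, ann)
  writeCalls(calls, file.path(outdir, "calls.tsv"))
  dir.create(file.path(outdir, "vcf"), showWarnings = FALSE)
  for (sm in unique(calls$sample)) {
    writeVariantVcf(calls[calls$sample == sm, , drop = FALSE],
                    file.path(outdir, "vcf", paste0(sm, ".vcf")))
  }
  passed <- calls[calls$pass & calls$category == "somatic", , drop = FALSE]
  callable <- sum(chromLengths(genome))
  mr <- mutationRate(passed, callable, samples = unique(calls$sample))
  jsonlite::write_json(list(per_sample = mr$perSample,
                            median_rate = mr$median),
                       file.path(outdir, "mutation_rate.json"),
                       auto_unbox = TRUE, digits = NA)
  rg <- recurrentGenes(passed[passed$non_silent, , drop = FALSE],
                       minSamples = config$minSamplesGene)
  utils::write.table(rg, file.path(outdir, "recurrent_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logLine(outdir, "callvar: ", nrow(passed), " passed somatic calls, ",
          nrow(rg), " recurrent gene(s)")
}

stageIntegrate <- function(config, outdir) {
  segs <- readSegments(file.path(outdir, "segments.tsv"))
  calls <- readCalls(file.path(outdir, "calls.tsv"))
  genome <- readGenome(file.path(outdir, "genome"))
  meta <- jsonlite::read_json(file.path(outdir, "meta.json"),
                              simplifyVector = TRUE)
  targetGene <- if (!is.na(config$targetGene)) config$targetGene
                else meta$targetGene
  g <- genes(genome)
  gi <- match(targetGene, GenomicRanges::mcols(g)$gene)
  if (is.na(gi)) stop("unknown target gene: ", targetGene)
  gene <- list(chrom = as.character(GenomicRanges::seqnames(g))[gi],
               start = GenomicRanges::start(g)[gi],
               end = GenomicRanges::end(g)[gi])
  samples <- meta$samples %||% sort(unique(calls$sample))
  statuses <- lapply(samples, function(sm) {
    inGene <- !is.na(calls$gene) & calls$gene == targetGene &
      calls$sample == sm & calls$pass
    som <- calls[inGene & calls$category == "somatic" & calls$non_silent, ,
                 drop = FALSE]
    somDf <- if (nrow(som)) {
      data.frame(label = paste0(som$chrom, ":", som$pos, som$ref, ">",
                                som$alt),
                 assay = "exome", af = som$t_vaf)
    } else NULL
    germ <- calls[inGene & calls$category == "germline" & calls$non_silent, ,
                  drop = FALSE]
    germLab <- if (nrow(germ)) paste0(germ$chrom, ":", germ$pos, germ$ref,
                                      ">", germ$alt) else NULL
    assembleStatus(sm, assays = c("array", "exome"), gene = gene,
                   segments = segs[segs$sample == sm, , drop = FALSE],
                   somatic = somDf, germline = germLab,
                   purity = config$purity,
                   subclonalAfFactor = config$subclonalAfFactor,
                   subclonalLogRFactor = config$subclonalLogRFactor,
                   wholeChromFraction = config$wholeChromFraction)
  })
  tab <- renderStatusTable(statuses)
  utils::write.table(tab, file.path(outdir, "status_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cs <- cohortSummary(statuses)
  jsonlite::write_json(cs, file.path(outdir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logLine(outdir, "integrate: ", cs$n_altered, "/", cs$n_samples,
          " samples altered (", cs$percent_altered, "%)")
  invisible(statuses)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, reading and writing all
#' intermediates under `outdir`; identical configuration and seed give
#' identical outputs, and running stages one at a time equals one `"all"`
#' run.
#'
#' @param config Configuration from [runConfig()].
#' @param outdir Output directory (created if needed).
#' @param stages Character vector drawn from `simulate`, `segment`,
#'   `callcna`, `callvar`, `integrate`, or `"all"`.
#' @return Invisibly, a list with the paths of the main artifacts.
#' @export
runPipeline <- function(config = runConfig(), outdir, stages = "all") {
  validateRunConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  order <- c("simulate", "segment", "callcna", "callvar", "integrate")
  if (identical(stages, "all")) stages <- order
  stages <- order[order %in% stages]
  if (length(stages) == 0L) stop("no valid stage requested")
  writeRunConfig(config, file.path(outdir, "config.json"))
  for (st in stages) {
    switch(st,
           simulate = stageSimulate(config, outdir),
           segment = stageSegment(config, outdir),
           callcna = stageCallCna(config, outdir),
           callvar = stageCallVar(config, outdir),
           integrate = stageIntegrate(config, outdir))
  }
  invisible(list(
    outdir = outdir,
    segments = file.path(outdir, "segments.tsv"),
    calls = file.path(outdir, "calls.tsv"),
    statusTable = file.path(outdir, "status_table.tsv"),
    cohortSummary = file.path(outdir, "cohort_summary.json"),
    log = file.path(outdir, "pipeline.log")))
}
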