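# Variant output: one VCF per sample pair (FILTER column carries cascade
# labels, INFO carries category / Fisher p / allelic fractions) plus a flat
# TSV mirror of the full call table.

#' @importFrom VariantAnnotation VCF VCFHeader writeVcf meta<- info<- fixed
#'   info readVcf
NULL

#' Write classified calls for one sample as VCF
#'
#' @param calls Call data.frame from [runCascade()] restricted to one sample.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(calls, path) {
  stopifnot(length(unique(calls$sample)) <= 1L)
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  hdr <- VariantAnnotation::VCFHeader(samples = character(0))
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1", "1", "1", "1", "1", "1"),
    Type = c("String", "Float", "Float", "Float", "Integer", "Integer",
             "Integer", "Integer"),
    Description = c("site category (germline/somatic/loh/unknown/filtered)",
                    "one-sided Fisher exact p for tumor alt enrichment",
                    "tumor variant allele fraction",
                    "normal variant allele fraction",
                    "tumor ref depth", "tumor alt depth",
                    "normal ref depth", "normal alt depth"),
    row.names = c("CAT", "SPV", "TVAF", "NVAF", "TRD", "TAD", "NRD", "NAD"))
  gr <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(calls$pos, calls$pos + nchar(calls$ref) - 1L))
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(calls$ref),
    ALT = Biostrings::DNAStringSetList(as.list(calls$alt)),
    QUAL = rep(NA_real_, nrow(calls)),
    FILTER = calls$filter)
  info <- S4Vectors::DataFrame(
    CAT = calls$category, SPV = calls$somatic_p,
    TVAF = calls$t_vaf, NVAF = calls$n_vaf,
    TRD = as.integer(calls$t_ref), TAD = as.integer(calls$t_alt),
    NRD = as.integer(calls$n_ref), NAD = as.integer(calls$n_alt))
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed, info = info,
                                exptData = list(header = hdr),
                                collapsed = TRUE)
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Write / read the flat call table mirror as TSV
#' @param calls Call data.frame from [runCascade()].
#' @param path TSV path.
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(sample = "character", chrom = "character",
                                   ref = "character", alt = "character"))
}
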