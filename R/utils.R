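# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' A single pipeline seed fans out to per-stage child seeds so that stages can
#' be rerun independently while the end-to-end run stays deterministic. The
#' derivation is a fixed affine hash kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param offset Integer stage offset (>= 0).
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.numeric(seed)) %% 1048573) * 1009 + as.numeric(offset) * 9973 + 1
  as.integer(s %% 2147483647)
}

# Lower median: for even n the smaller of the two middle order statistics.
lowerMedian <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  unname(x[floor((n + 1) / 2)])
}

# NA-safe scalar defaulting
`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a base-pair size the way cohort tables print it ("15 Mb", "0.34 Mb").
formatMb <- function(bp) {
  mb <- signif(bp / 1e6, 2)
  paste0(format(mb, trim = TRUE, scientific = FALSE), " Mb")
}
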