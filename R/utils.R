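# Internal helpers shared across modules.

#' Single-base substitution classes
#'
#' The six pyrimidine-referenced substitution classes used throughout the
#' package, in COSMIC order. Reverse complements are collapsed, so e.g.
#' A>C calls are counted as T>G.
#'
#' @format Character vector of length 6.
#' @export
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

BASES <- c("A", "C", "G", "T")

#' @noRd
.complementBase <- function(x) chartr("ACGTN", "TGCAN", x)

# Reverse complement for a character vector of short sequences.
#' @noRd
.revcomp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

#' @noRd
.assertBases <- function(x, what) {
  bad <- !(x %in% BASES)
  if (any(bad)) {
    stop(sprintf("%s must be one of A/C/G/T (offending value: '%s')",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

# Wilson score interval for a binomial proportion.
#' @noRd
.wilsonCI <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

# Extract one contig as a plain character string, with existence check.
#' @noRd
.contigString <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    stop(sprintf("contig '%s' not present in the reference", contig),
         call. = FALSE)
  }
  as.character(genome[[contig]])
}

# Vectorized slice of the reference; start/end 1-based inclusive.
# Out-of-range requests are an error (callers exclude edge sites first).
#' @noRd
.refSlice <- function(contigSeq, start, end) {
  if (any(start < 1L) || any(end > nchar(contigSeq))) {
    stop("reference window extends beyond the contig", call. = FALSE)
  }
  substring(contigSeq, start, end)
}

# Validate a variant call / pileup mismatch table's core columns.
#' @noRd
.checkCalls <- function(calls, requireDepth = TRUE) {
  need <- c("contig", "pos", "ref", "alt")
  if (requireDepth) need <- c(need, "ad", "dp")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("call table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(calls)) {
    .assertBases(calls$ref, "ref")
    .assertBases(calls$alt, "alt")
    if (any(calls$ref == calls$alt)) {
      stop("ref and alt must differ", call. = FALSE)
    }
    if (requireDepth && any(calls$dp < calls$ad)) {
      stop("dp must be >= ad", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @noRd
.callKey <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' @noRd
.siteKey <- function(calls) {
  paste(calls$contig, calls$pos, calls$alt, sep = ":")
}

# Empty variant-call table with canonical column types.
#' @noRd
.emptyCalls <- function(platform = character(0)) {
  data.frame(
    contig = character(0), pos = integer(0), ref = character(0),
    alt = character(0), ad = integer(0), dp = integer(0),
    af = numeric(0), platform = character(0),
    stringsAsFactors = FALSE
  )
}
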