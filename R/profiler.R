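# Per-site mismatch pileups from QC-passed reads, allele-depth
# stratification, platform-specific site definition, AD recalculation for
# variant calls, and binomial coverage downsampling.

#' Collapse an SNV into its pyrimidine-referenced substitution class
#'
#' Reverse complements are indistinguishable in sequencing data, so the 12
#' ordered (ref, alt) pairs collapse to 6 classes: purine-referenced pairs
#' are complemented (A>C becomes T>G), pyrimidine-referenced pairs pass
#' through.
#'
#' @param ref,alt single reference/alternate bases (vectorised).
#' @return Character vector of classes from [SBS_CLASSES].
#' @examples
#' collapseSBS("A", "C")  # "T>G"
#' collapseSBS("C", "T")  # "C>T"
#' @export
collapseSBS <- function(ref, alt) {
  if (length(ref) == 0L) return(character(0))
  .assertBases(ref, "ref")
  .assertBases(alt, "alt")
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, .complementBase(ref), ref)
  a <- ifelse(purine, .complementBase(alt), alt)
  paste0(r, ">", a)
}

# Base count matrix (4 x contig length) and coverage from all-M reads.
#' @noRd
.pileupCounts <- function(reads, contigSeq) {
  L <- nchar(contigSeq)
  M <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  cov <- integer(L)
  for (i in seq_len(nrow(reads))) {
    p0 <- reads$pos[i]
    b <- strsplit(reads$bases[i], "")[[1L]]
    posv <- p0 + seq_along(b) - 1L
    if (p0 < 1L || posv[length(posv)] > L) {
      stop("read '", reads$name[i], "' maps beyond the contig end",
           call. = FALSE)
    }
    idx <- match(b, BASES)
    ok <- !is.na(idx)
    M[cbind(idx[ok], posv[ok])] <- M[cbind(idx[ok], posv[ok])] + 1L
    cov[posv] <- cov[posv] + 1L
  }
  list(counts = M, coverage = cov)
}

#' Build per-site mismatch pileups from filtered reads
#'
#' For every reference position covered by at least one kept read, counts
#' each non-reference base; one row is emitted per (position, alt allele)
#' pair, with `ad` the number of supporting reads and `dp` the total kept
#' reads covering the position. Positions whose reference base is N are
#' excluded. Reads must have passed [readQC()] (all-M alignments).
#'
#' @param reads read-record data.frame (columns contig, pos, bases, name).
#' @param genome a [Biostrings::DNAStringSet] reference.
#' @param platform platform label for the output.
#' @return A list: `mismatches` (PileupMismatch data.frame: contig, pos,
#'   ref, alt, ad, dp, platform) and `coverage` (per-contig integer
#'   vectors of kept-read depth).
#' @export
pileupMismatches <- function(reads, genome, platform = "sample") {
  mm <- list()
  coverage <- list()
  for (contig in unique(reads$contig)) {
    contigSeq <- .contigString(genome, contig)
    sub <- reads[reads$contig == contig, , drop = FALSE]
    pc <- .pileupCounts(sub, contigSeq)
    coverage[[contig]] <- pc$coverage
    refIdx <- match(strsplit(contigSeq, "")[[1L]], BASES)  # NA for N
    rows <- list()
    for (b in seq_along(BASES)) {
      sel <- which(pc$counts[b, ] > 0L & !is.na(refIdx) & refIdx != b)
      if (length(sel)) {
        rows[[BASES[b]]] <- data.frame(
          contig = contig, pos = sel,
          ref = BASES[refIdx[sel]], alt = BASES[b],
          ad = pc$counts[b, sel], dp = pc$coverage[sel],
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) mm[[contig]] <- do.call(rbind, rows)
  }
  mismatches <- if (length(mm)) do.call(rbind, mm) else .emptyCalls()[
    , c("contig", "pos", "ref", "alt", "ad", "dp")]
  if (nrow(mismatches)) {
    mismatches <- mismatches[order(mismatches$contig, mismatches$pos,
                                   mismatches$alt), , drop = FALSE]
  }
  mismatches$platform <- rep(platform, nrow(mismatches))
  rownames(mismatches) <- NULL
  list(mismatches = mismatches, coverage = coverage)
}

#' Platform-specific mismatch sites
#'
#' Returns the sites (keyed by contig, position, alt allele) mismatched on
#' platform `a` and absent from platform `b`, restricted to positions
#' where `b` has coverage of at least `minOtherDepth` — absence is
#' unverifiable at uncovered positions. Call with the arguments swapped
#' for the other platform's specific sites.
#'
#' @param a,b PileupMismatch data.frames for the two platforms.
#' @param covB per-contig coverage for platform `b`, either the `coverage`
#'   element returned by [pileupMismatches()] / [simulatePileups()] or a
#'   data.frame(contig, pos, dp). Required unless `minOtherDepth = 0`.
#' @param minOtherDepth minimum depth on `b` for absence to count.
#' @return The subset of `a` specific to its platform.
#' @export
platformSpecificSites <- function(a, b, covB = NULL, minOtherDepth = 1L) {
  .checkCalls(a); .checkCalls(b)
  out <- a[!(.siteKey(a) %in% .siteKey(b)), , drop = FALSE]
  if (minOtherDepth > 0L) {
    if (is.null(covB)) {
      stop("covB is required when minOtherDepth > 0", call. = FALSE)
    }
    depthAt <- if (is.data.frame(covB)) {
      key <- paste(covB$contig, covB$pos)
      dp <- covB$dp[match(paste(out$contig, out$pos), key)]
      ifelse(is.na(dp), 0L, dp)
    } else {
      mapply(function(ctg, p) {
        v <- covB[[ctg]]
        if (is.null(v) || p > length(v)) 0L else v[p]
      }, out$contig, out$pos)
    }
    out <- out[depthAt >= minOtherDepth, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Stratify mismatch sites by substitution class and allele depth
#'
#' @param sites PileupMismatch data.frame from one platform.
#' @param adMax top AD bin; sites with `ad > adMax` accumulate in it
#'   (conservation over truncation).
#' @param platform label; defaults to the table's platform column.
#' @return An [ADMatrix-class].
#' @export
adSpectrum <- function(sites, adMax = 25L, platform = NULL) {
  .checkCalls(sites)
  if (is.null(platform)) {
    platform <- if (nrow(sites) && "platform" %in% names(sites)) {
      sites$platform[1L]
    } else "sample"
  }
  cnt <- matrix(0L, nrow = 6L, ncol = adMax,
                dimnames = list(SBS_CLASSES, as.character(seq_len(adMax))))
  if (nrow(sites)) {
    if (any(sites$ad < 1L)) stop("sites must have ad >= 1", call. = FALSE)
    cls <- collapseSBS(sites$ref, sites$alt)
    bin <- pmin(sites$ad, adMax)
    tab <- table(factor(cls, levels = SBS_CLASSES),
                 factor(bin, levels = seq_len(adMax)))
    cnt[] <- as.integer(tab)
  }
  methods::new("ADMatrix", counts = cnt, platform = platform)
}

#' Fraction of mismatches that are T>G at a given allele depth
#'
#' @param m an [ADMatrix-class].
#' @param ad the AD stratum.
#' @return `counts["T>G", ad] / sum(counts[, ad])`, or `NA` when no
#'   mismatches were observed at that AD (undefined, not zero).
#' @export
tgFraction <- function(m, ad) {
  stopifnot(methods::is(m, "ADMatrix"))
  cnt <- counts(m)
  if (ad < 1L || ad > ncol(cnt)) stop("ad outside the matrix range",
                                      call. = FALSE)
  tot <- sum(cnt[, ad])
  if (tot == 0L) NA_real_ else unname(cnt["T>G", ad] / tot)
}

#' Allele fraction from allele depth
#'
#' @param ad alternate allele depth(s).
#' @param dp total depth(s), must be positive.
#' @return `ad/dp`.
#' @examples
#' afFromAD(2, 47)  # 0.04255..., i.e. a ~4.25% minimum AF at 47X
#' @export
afFromAD <- function(ad, dp) {
  if (any(dp <= 0)) stop("dp must be positive", call. = FALSE)
  if (any(ad < 0) || any(ad > dp)) stop("need 0 <= ad <= dp", call. = FALSE)
  ad / dp
}

#' Recalculate allele depths of variant calls from read pileups
#'
#' Replaces each call's ad/dp with the pileup support observed in the
#' filtered reads and retains only calls with recomputed `ad >= minAD`
#' (default 2). Calls at uncovered positions get ad = 0 and are dropped.
#'
#' @param calls variant-call data.frame.
#' @param reads QC-passed read-record data.frame.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param minAD retention threshold on the recomputed alternate depth.
#' @return A list with `calls` (retained, ad/dp/af updated) and `dropped`
#'   (count).
#' @export
recalculateAD <- function(calls, reads, genome, minAD = 2L) {
  .checkCalls(calls, requireDepth = FALSE)
  if (nrow(reads) == 0L) {
    warning("empty alignment stream: all calls dropped", call. = FALSE)
    return(list(calls = calls[0, , drop = FALSE], dropped = nrow(calls)))
  }
  ad <- integer(nrow(calls))
  dp <- integer(nrow(calls))
  for (contig in unique(calls$contig)) {
    contigSeq <- .contigString(genome, contig)
    inC <- calls$contig == contig
    sub <- reads[reads$contig == contig, , drop = FALSE]
    pc <- .pileupCounts(sub, contigSeq)
    p <- calls$pos[inC]
    ad[inC] <- pc$counts[cbind(match(calls$alt[inC], BASES), p)]
    dp[inC] <- pc$coverage[p]
  }
  calls$ad <- ad
  calls$dp <- dp
  calls$af <- ifelse(dp > 0L, ad / dp, NA_real_)
  keep <- ad >= minAD
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, dropped = sum(!keep))
}

#' Binomial thinning of mismatch sites to a lower target coverage
#'
#' Simulates the pileups that would have been retained had the platform
#' been sequenced at `targetCov` instead of `sourceCov`: each supporting
#' read and each reference read is retained independently with
#' probability `targetCov/sourceCov`; sites whose thinned ad reaches 0
#' are removed.
#'
#' @param sites PileupMismatch data.frame.
#' @param sourceCov,targetCov original and target mean coverage,
#'   `0 < targetCov <= sourceCov`.
#' @param seed optional integer seed for reproducibility.
#' @return The thinned PileupMismatch data.frame.
#' @export
downsampleSites <- function(sites, sourceCov, targetCov, seed = NULL) {
  .checkCalls(sites)
  if (targetCov <= 0 || targetCov > sourceCov) {
    stop("need 0 < targetCov <= sourceCov", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- targetCov / sourceCov
  if (p == 1) return(sites)
  n <- nrow(sites)
  adNew <- stats::rbinom(n, sites$ad, p)
  refNew <- stats::rbinom(n, sites$dp - sites$ad, p)
  sites$ad <- adNew
  sites$dp <- adNew + refNew
  out <- sites[sites$ad > 0L, , drop = FALSE]
  out$af <- ifelse(out$dp > 0L, out$ad / out$dp, NA_real_)
  rownames(out) <- NULL
  out
}

#' Calls exclusive to one platform's callset
#'
#' @param a,b variant-call data.frames on the same genome build.
#' @return Calls in `a` with no (contig, pos, ref, alt) match in `b`.
#' @export
platformExclusiveCalls <- function(a, b) {
  .checkCalls(a, requireDepth = FALSE)
  .checkCalls(b, requireDepth = FALSE)
  out <- a[!(.callKey(a) %in% .callKey(b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
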