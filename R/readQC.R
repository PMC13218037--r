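# Stringent read-level trimming and alignment filtering that isolates
# platform-specific base-call errors from generic sequencing noise. The
# rules are deliberately harsher than standard pre-variant-calling QC: the
# point is a clean mismatch substrate, not maximal yield.

#' Trimming policy for a read-length class
#'
#' Fixed parameters of the read-level cleaning stage: the final
#' `tailTrim` bases of every read are removed (read-end quality
#' degradation), the first `headTrim` bases are removed (possible
#' read-start adapter contamination; 8 for 101-bp reads, 12 for 151/250-bp
#' reads), mean base quality is then scanned in `window`-bp sliding
#' windows and the read is cut at the first window whose mean Phred drops
#' below `windowThreshold`, and finally reads shorter than `minLength`
#' (65 for the 101-bp class, 100 for 151/250) are discarded.
#'
#' @param lengthClass one of 101, 151, 250 (nominal read length).
#' @return A list with elements tailTrim, headTrim, window,
#'   windowThreshold, minLength, lengthClass.
#' @export
trimPolicy <- function(lengthClass) {
  lengthClass <- as.integer(lengthClass)
  if (!lengthClass %in% c(101L, 151L, 250L)) {
    stop("lengthClass must be one of 101, 151, 250", call. = FALSE)
  }
  list(
    tailTrim = 5L,
    headTrim = if (lengthClass == 101L) 8L else 12L,
    window = 10L,
    windowThreshold = 25,
    minLength = if (lengthClass == 101L) 65L else 100L,
    lengthClass = lengthClass
  )
}

#' @noRd
.policyFor <- function(reads, policy) {
  if (!is.null(policy)) {
    rep(list(policy), nrow(reads))
  } else {
    lapply(reads$lengthClass, trimPolicy)
  }
}

#' Fixed head/tail trimming
#'
#' Removes the final `tailTrim` bases and the first `headTrim` bases of
#' each read (bases and qualities identically); for mapped all-M reads the
#' alignment start is shifted by the head trim so positions stay correct.
#' Reads too short for the combined trims are discarded and counted.
#'
#' @param reads read-record data.frame from [readAlignments()].
#' @param policy optional single [trimPolicy()] applied to all reads;
#'   default derives the policy from each read's `lengthClass`.
#' @return A list with `reads` (the trimmed table) and `discarded`
#'   (number of reads shorter than the combined trims).
#' @export
fixedTrim <- function(reads, policy = NULL) {
  pol <- .policyFor(reads, policy)
  len <- nchar(reads$bases)
  head <- vapply(pol, `[[`, integer(1), "headTrim")
  tail <- vapply(pol, `[[`, integer(1), "tailTrim")
  keep <- len >= head + tail + 1L
  out <- reads[keep, , drop = FALSE]
  h <- head[keep]
  newLen <- len[keep] - h - tail[keep]
  out$bases <- substr(out$bases, h + 1L, h + newLen)
  out$quals <- mapply(function(q, hh, nl) q[(hh + 1L):(hh + nl)],
                      out$quals, h, newLen, SIMPLIFY = FALSE)
  if ("pos" %in% names(out)) out$pos <- out$pos + h
  rownames(out) <- NULL
  list(reads = out, discarded = sum(!keep))
}

# First failing window start (1-based) for one quality vector, or 0L.
#' @noRd
.firstFailingWindow <- function(q, window, threshold) {
  n <- length(q)
  if (n < window) return(0L)
  cs <- cumsum(c(0, q))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  idx <- which(means < threshold)
  if (length(idx)) idx[1L] else 0L
}

#' Sliding-window quality trimming
#'
#' Scans `window`-bp windows left to right (step 1 base; only windows
#' entirely within the read). At the first window whose mean Phred quality
#' drops below the threshold, the read is cut at that window's leftmost
#' position and the rest discarded; reads with no failing window are
#' unchanged. Runs on the fixed-trimmed read.
#'
#' @inheritParams fixedTrim
#' @return The read table with trimmed bases/quals (possibly empty reads,
#'   handled by [lengthFilter()]).
#' @export
qualitySlidingTrim <- function(reads, policy = NULL) {
  pol <- .policyFor(reads, policy)
  cut <- mapply(function(q, p) {
    .firstFailingWindow(q, p$window, p$windowThreshold)
  }, reads$quals, pol)
  hit <- cut > 0L
  if (any(hit)) {
    reads$bases[hit] <- substr(reads$bases[hit], 1L, cut[hit] - 1L)
    reads$quals[hit] <- mapply(function(q, k) q[seq_len(k - 1L)],
                               reads$quals[hit], cut[hit], SIMPLIFY = FALSE)
  }
  reads
}

#' Minimum-length filter after trimming
#'
#' Keeps reads with at least `minLength` bases for their length class
#' (inclusive comparison).
#'
#' @inheritParams fixedTrim
#' @return A list with `reads` (kept) and `discarded` (count).
#' @export
lengthFilter <- function(reads, policy = NULL) {
  pol <- .policyFor(reads, policy)
  minLen <- vapply(pol, `[[`, integer(1), "minLength")
  keep <- nchar(reads$bases) >= minLen
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, discarded = sum(!keep))
}

#' Alignment-level read filter
#'
#' Discards reads that are unmapped, are duplicates, are not mapped in a
#' proper pair, are supplementary alignments, have mapping quality below
#' 60, or whose CIGAR reports indel or clipping operations (I, D, S, H).
#' Rules are evaluated in that fixed order and the first failing rule is
#' recorded as the reason code; any order yields the same kept set.
#'
#' @param reads read-record data.frame.
#' @param minMapq minimum Phred-scaled mapping quality (kept iff >= 60 by
#'   default).
#' @return A list with `reads` (kept), `discarded` (table of name +
#'   reason), and `reasonCounts` (named integer vector over reason codes).
#' @export
alignmentFilter <- function(reads, minMapq = 60L) {
  reason <- rep(NA_character_, nrow(reads))
  fail <- function(cond, code) {
    hit <- is.na(reason) & cond
    reason[hit] <<- code
  }
  fail(!reads$mapped, "unmapped")
  fail(reads$duplicate, "duplicate")
  fail(!reads$properPair, "proper_pair")
  fail(reads$supplementary, "supplementary")
  fail(reads$mapq < minMapq, "mapq")
  fail(grepl("[IDSH]", reads$cigar), "cigar")
  keep <- is.na(reason)
  codes <- c("unmapped", "duplicate", "proper_pair", "supplementary",
             "mapq", "cigar")
  reasonCounts <- vapply(codes, function(cd) sum(reason == cd, na.rm = TRUE),
                         integer(1))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       discarded = data.frame(name = reads$name[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE),
       reasonCounts = reasonCounts)
}

#' Full read-level QC pipeline
#'
#' Applies [alignmentFilter()] (flags/MAPQ/CIGAR; run first so surviving
#' reads are all-M and trims shift positions trivially — the kept set is
#' identical under any order), then [fixedTrim()], [qualitySlidingTrim()]
#' and [lengthFilter()].
#'
#' @inheritParams fixedTrim
#' @param minMapq minimum mapping quality, see [alignmentFilter()].
#' @return A list with `reads` (the clean table) and `counts` (named
#'   discard counts per stage/reason).
#' @export
readQC <- function(reads, policy = NULL, minMapq = 60L) {
  af <- alignmentFilter(reads, minMapq = minMapq)
  ft <- fixedTrim(af$reads, policy)
  qt <- qualitySlidingTrim(ft$reads, policy)
  lf <- lengthFilter(qt, policy)
  counts <- c(af$reasonCounts,
              too_short_for_trims = ft$discarded,
              below_min_length = lf$discarded)
  list(reads = lf$reads, counts = counts)
}
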