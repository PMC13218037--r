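# Trinucleotide (COSMIC 96-channel) spectra, the 16-context N[T>G]N view,
# flanking base-composition profiles against the genome background, and
# k-mer motif ranking around calls.

# All 96 channel labels in canonical order: class-major, then 5' base, then
# 3' base, each in A,C,G,T order.
#' @noRd
.channels96 <- function() {
  unlist(lapply(SBS_CLASSES, function(cl) {
    as.vector(t(outer(BASES, BASES, function(l, r) {
      sprintf("%s[%s]%s", l, cl, r)
    })))
  }))
}

#' @noRd
.channels16TG <- function() {
  as.vector(t(outer(BASES, BASES, function(l, r) {
    sprintf("%s[T>G]%s", l, r)
  })))
}

# Pyrimidine-frame context fields for each call: class, left and right
# neighbours. NA where the trinucleotide leaves the contig or touches N.
#' @noRd
.contextFrame <- function(genome, calls) {
  n <- nrow(calls)
  cls <- collapseSBS(calls$ref, calls$alt)
  left <- rep(NA_character_, n)
  right <- rep(NA_character_, n)
  for (contig in unique(calls$contig)) {
    cs <- .contigString(genome, contig)
    inC <- which(calls$contig == contig)
    p <- calls$pos[inC]
    ok <- p >= 2L & p <= nchar(cs) - 1L
    l <- r <- rep(NA_character_, length(inC))
    if (any(ok)) {
      l[ok] <- substring(cs, p[ok] - 1L, p[ok] - 1L)
      r[ok] <- substring(cs, p[ok] + 1L, p[ok] + 1L)
    }
    left[inC] <- l
    right[inC] <- r
  }
  purine <- calls$ref %in% c("A", "G")
  l2 <- ifelse(purine, .complementBase(right), left)
  r2 <- ifelse(purine, .complementBase(left), right)
  bad <- is.na(l2) | is.na(r2) | !(l2 %in% BASES) | !(r2 %in% BASES)
  l2[bad] <- NA_character_
  r2[bad] <- NA_character_
  data.frame(class = cls, left = l2, right = r2,
             stringsAsFactors = FALSE)
}

#' Trinucleotide channel of each call (COSMIC 96-channel format)
#'
#' Classifies each SNV into its pyrimidine-oriented trinucleotide channel
#' L[ref>alt]R: for purine-referenced calls the trinucleotide and the
#' alternate allele are reverse-complemented before classification, so
#' e.g. TAT with A>C maps to A[T>G]A.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param calls variant-call data.frame.
#' @return Character vector of channel labels, NA for calls whose context
#'   touches an N or a contig edge (the count of these is attached as
#'   `attr(x, "excluded")`).
#' @export
trinucleotideChannel <- function(genome, calls) {
  .checkCalls(calls, requireDepth = FALSE)
  cf <- .contextFrame(genome, calls)
  out <- ifelse(is.na(cf$left), NA_character_,
                sprintf("%s[%s]%s", cf$left, cf$class, cf$right))
  attr(out, "excluded") <- sum(is.na(out))
  out
}

#' Mutation spectrum over trinucleotide channels
#'
#' Counts classifiable calls per channel, either over all 96 COSMIC
#' channels or restricted to the 16 N[T>G]N contexts.
#'
#' @inheritParams trinucleotideChannel
#' @param mode `"96"` or `"16TG"`.
#' @return Named integer vector over the channels (in canonical order).
#' @export
mutationSpectrum <- function(genome, calls, mode = c("96", "16TG")) {
  mode <- match.arg(mode)
  chan <- trinucleotideChannel(genome, calls)
  lev <- if (mode == "96") .channels96() else .channels16TG()
  if (mode == "16TG") {
    chan <- chan[!is.na(chan) & grepl("T>G", chan, fixed = TRUE)]
  }
  tab <- table(factor(chan[!is.na(chan)], levels = lev))
  out <- as.integer(tab)
  names(out) <- lev
  out
}

#' Base composition around calls versus the genome background
#'
#' At each relative offset within `flank` bases of the variant position
#' (offset 0, the variant base itself, is excluded), computes the
#' fraction of calls carrying each nucleotide, with Wilson 95% confidence
#' intervals, alongside the genome-wide background base fractions
#' (computed over the full reference, N excluded). Windows are flipped
#' into the pyrimidine frame for purine-referenced calls so that artifact
#' motifs from both strands co-accumulate; `orient = "as-read"` keeps the
#' reference strand as is.
#'
#' @inheritParams trinucleotideChannel
#' @param flank window half-width in bases (default 5, i.e. a 10-base
#'   window).
#' @param conf confidence level of the Wilson intervals.
#' @param orient `"pyrimidine"` (default) or `"as-read"`.
#' @return A data.frame with columns offset, base, count, fraction,
#'   lower, upper, background, n (calls used); calls whose window crosses
#'   a contig edge or an N are excluded and counted in
#'   `attr(x, "excluded")`.
#' @export
baseComposition <- function(genome, calls, flank = 5L, conf = 0.95,
                            orient = c("pyrimidine", "as-read")) {
  orient <- match.arg(orient)
  win <- .extractWindows(genome, calls, flank = flank, orient = orient)
  used <- win[!is.na(win)]
  n <- length(used)
  offsets <- c(-(flank:1), 1:flank)
  bg <- .backgroundFractions(genome)
  rows <- list()
  mat <- if (n) do.call(rbind, strsplit(used, "")) else
    matrix(character(0), 0, 2L * flank)
  for (j in seq_along(offsets)) {
    cnt <- if (n) table(factor(mat[, j], levels = BASES)) else
      table(factor(character(0), levels = BASES))
    frac <- if (n) as.numeric(cnt) / n else rep(NA_real_, 4L)
    ci <- if (n) .wilsonCI(as.numeric(cnt), n, conf) else
      matrix(NA_real_, 4L, 2L, dimnames = list(NULL, c("lower", "upper")))
    rows[[j]] <- data.frame(
      offset = offsets[j], base = BASES, count = as.integer(cnt),
      fraction = frac, lower = ci[, "lower"], upper = ci[, "upper"],
      background = unname(bg[BASES]), n = n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(is.na(win))
  out
}

#' @noRd
.backgroundFractions <- function(genome) {
  freq <- colSums(Biostrings::letterFrequency(genome, letters = BASES))
  freq / sum(freq)
}

#' Ranked k-mer motifs adjacent to calls
#'
#' Counts the k-mer immediately 3' (`side = "downstream"`) or 5'
#' (`side = "upstream"`) of each call in the pyrimidine frame, sorted by
#' count descending with a deterministic lexicographic tie-break.
#'
#' @inheritParams trinucleotideChannel
#' @param k k-mer length (>= 1).
#' @param side `"downstream"` (3' of the variant) or `"upstream"`.
#' @return Named integer vector of counts, most frequent first.
#' @export
kmerMotifs <- function(genome, calls, k = 4L,
                       side = c("downstream", "upstream")) {
  side <- match.arg(side)
  stopifnot(k >= 1L)
  .checkCalls(calls, requireDepth = FALSE)
  n <- nrow(calls)
  kmer <- rep(NA_character_, n)
  purine <- calls$ref %in% c("A", "G")
  # in the pyrimidine frame, "downstream" of a purine-referenced call is
  # upstream on the reference strand, reverse-complemented
  for (contig in unique(calls$contig)) {
    cs <- .contigString(genome, contig)
    L <- nchar(cs)
    inC <- which(calls$contig == contig)
    p <- calls$pos[inC]
    pur <- purine[inC]
    wantRight <- (side == "downstream") != pur  # XOR
    s <- ifelse(wantRight, p + 1L, p - k)
    e <- ifelse(wantRight, p + k, p - 1L)
    ok <- s >= 1L & e <= L
    km <- rep(NA_character_, length(inC))
    if (any(ok)) km[ok] <- substring(cs, s[ok], e[ok])
    km[pur] <- .revcomp(km[pur])
    kmer[inC] <- km
  }
  kmer <- kmer[!is.na(kmer) & !grepl("N", kmer, fixed = TRUE)]
  tab <- table(kmer)
  cnt <- as.integer(tab)
  nm <- names(tab)
  ord <- order(-cnt, nm)
  out <- cnt[ord]
  names(out) <- nm[ord]
  out
}
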