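# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-element loops, enumeration) so they cannot share
# a defect with the vectorised implementations they check.

BASES4 <- c("A", "C", "G", "T")

comp1 <- function(x) chartr("ACGT", "TGCA", x)

revcomp1 <- function(x) {
  vapply(x, function(s) {
    paste(rev(comp1(strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Naive sliding-window quality trim: test every window by direct mean.
naiveSlidingTrim <- function(quals, window = 10L, threshold = 25) {
  n <- length(quals)
  if (n >= window) {
    for (i in 1:(n - window + 1L)) {
      if (mean(quals[i:(i + window - 1L)]) < threshold) {
        return(i - 1L)  # retained prefix length
      }
    }
  }
  n
}

# Naive per-column pileup counter over all-M reads.
naivePileup <- function(reads, contigSeq) {
  L <- nchar(contigSeq)
  refv <- strsplit(contigSeq, "")[[1]]
  out <- NULL
  for (p in 1:L) {
    column <- character(0)
    for (i in seq_len(nrow(reads))) {
      s <- reads$pos[i]
      e <- s + nchar(reads$bases[i]) - 1L
      if (s <= p && p <= e) {
        column <- c(column, substr(reads$bases[i], p - s + 1L, p - s + 1L))
      }
    }
    if (!length(column) || !(refv[p] %in% BASES4)) next
    for (b in setdiff(BASES4, refv[p])) {
      ad <- sum(column == b)
      if (ad > 0) {
        out <- rbind(out, data.frame(
          pos = p, ref = refv[p], alt = b, ad = ad, dp = length(column),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Dictionary of all 12 x 16 raw (trinucleotide, alt) combinations to their
# pyrimidine channel, built by enumerating the 96 channels and writing out
# each channel's two strand representations.
channelDictionary <- function() {
  dict <- list()
  for (cl in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")) {
    ref <- substr(cl, 1, 1)
    alt <- substr(cl, 3, 3)
    for (l in BASES4) {
      for (r in BASES4) {
        chan <- sprintf("%s[%s]%s", l, cl, r)
        dict[[paste(l, ref, r, alt)]] <- chan
        dict[[paste(comp1(r), comp1(ref), comp1(l), comp1(alt))]] <- chan
      }
    }
  }
  dict
}

# Naive pooled two-proportion z via prop.test's chi-square (z^2 identity).
naiveZ <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  chi <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$statistic)
  sign(p1 - p2) * sqrt(unname(chi))
}

# Exact log-LR null by full enumeration of all 4^npos windows.
naiveNull <- function(pwmNova, pwmHiseq) {
  pn <- pwmProbs(pwmNova)
  ph <- pwmProbs(pwmHiseq)
  npos <- ncol(pn)
  grid <- expand.grid(rep(list(1:4), npos))
  val <- numeric(nrow(grid))
  pr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    idx <- as.integer(grid[i, ])
    val[i] <- sum(log(pn[cbind(idx, 1:npos)]) -
                    log(ph[cbind(idx, 1:npos)]))
    pr[i] <- prod(ph[cbind(idx, 1:npos)])
  }
  list(value = val, prob = pr)
}

# Random all-M read table over a genome, for pileup/QC property tests.
randomReads <- function(contigSeq, nReads = 10L, readLen = 20L,
                        mutRate = 0.1, contig = "c1") {
  L <- nchar(contigSeq)
  starts <- sample.int(L - readLen + 1L, nReads, replace = TRUE)
  bases <- vapply(starts, function(s) {
    b <- strsplit(substr(contigSeq, s, s + readLen - 1L), "")[[1]]
    mut <- runif(readLen) < mutRate
    b[mut] <- vapply(b[mut], function(x) sample(setdiff(BASES4, x), 1L),
                     character(1))
    paste(b, collapse = "")
  }, character(1))
  reads <- data.frame(
    name = sprintf("r%03d", seq_len(nReads)), contig = contig,
    pos = starts, mapq = 60L, mapped = TRUE, properPair = TRUE,
    supplementary = FALSE, duplicate = FALSE,
    cigar = paste0(readLen, "M"), bases = bases, lengthClass = 101L,
    stringsAsFactors = FALSE)
  reads$quals <- rep(list(rep(37L, readLen)), nReads)
  reads
}

# A one-row call table.
oneCall <- function(contig, pos, ref, alt, ad = 5L, dp = 20L,
                    platform = "nova") {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             ad = as.integer(ad), dp = as.integer(dp), af = ad / dp,
             platform = platform, stringsAsFactors = FALSE)
}

smallGenome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(g) <- paste0("c", seq_along(seqs))
  g
}
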