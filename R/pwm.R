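# The PWM likelihood-ratio artifact filter: per-platform position weight
# matrices over 8-base windows around calls, log-likelihood-ratio scoring,
# an exact convolution null, and callset correction.

# Windows of 2*flank bases around each call, variant base excluded,
# flipped into the pyrimidine frame unless orient = "as-read".
# NA where the window leaves the contig or contains N.
#' @noRd
.extractWindows <- function(genome, calls, flank = 4L,
                            orient = "pyrimidine") {
  n <- nrow(calls)
  win <- rep(NA_character_, n)
  purine <- calls$ref %in% c("A", "G")
  for (contig in unique(calls$contig)) {
    cs <- .contigString(genome, contig)
    L <- nchar(cs)
    inC <- which(calls$contig == contig)
    p <- calls$pos[inC]
    ok <- p - flank >= 1L & p + flank <= L
    w <- rep(NA_character_, length(inC))
    if (any(ok)) {
      w[ok] <- paste0(substring(cs, p[ok] - flank, p[ok] - 1L),
                      substring(cs, p[ok] + 1L, p[ok] + flank))
    }
    if (orient == "pyrimidine") {
      pur <- purine[inC]
      w[pur] <- .revcomp(w[pur])
    }
    win[inC] <- w
  }
  win[!is.na(win) & grepl("N", win, fixed = TRUE)] <- NA_character_
  win
}

#' Extract the flanking window around each call
#'
#' Concatenates the `flank` bases 5' and `flank` bases 3' of the variant
#' position (the variant base itself is excluded — it is constant within a
#' substitution class and carries no information). Purine-referenced
#' calls are reverse-complemented into the pyrimidine frame so both
#' strands of the collapsed class share one coordinate system.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param calls variant-call data.frame.
#' @param flank half-width (default 4, giving the 8-base window).
#' @param orient `"pyrimidine"` (default) or `"as-read"`.
#' @return Character vector of 2*flank-base windows; NA (counted in
#'   `attr(x, "excluded")`) where the window crosses a contig edge or
#'   contains N.
#' @export
extractWindow <- function(genome, calls, flank = 4L,
                          orient = c("pyrimidine", "as-read")) {
  orient <- match.arg(orient)
  .checkCalls(calls, requireDepth = FALSE)
  win <- .extractWindows(genome, calls, flank = flank, orient = orient)
  attr(win, "excluded") <- sum(is.na(win))
  win
}

#' Build a position weight matrix from flanking windows
#'
#' Column j's probability of base b is (count_j(b) + pseudocount) /
#' (n + 4 * pseudocount). The Laplace pseudocount (default 1) guarantees
#' strictly positive probabilities and hence finite log-likelihood
#' ratios.
#'
#' @param windows character vector of equal-length A/C/G/T windows (NAs
#'   are dropped).
#' @param pseudocount Laplace pseudocount.
#' @param sbsClass,platform labels stored with the PWM.
#' @return A [PWM-class].
#' @export
buildPWM <- function(windows, pseudocount = 1, sbsClass = NA_character_,
                     platform = NA_character_) {
  windows <- windows[!is.na(windows)]
  if (!length(windows)) {
    stop("no training windows: supply a larger callset or pool classes",
         call. = FALSE)
  }
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L) stop("windows must share one length",
                               call. = FALSE)
  if (wlen %% 2L != 0L) stop("window length must be even", call. = FALSE)
  mat <- do.call(rbind, strsplit(windows, ""))
  if (!all(mat %in% BASES)) stop("windows must contain only A/C/G/T",
                                 call. = FALSE)
  n <- length(windows)
  cnt <- apply(mat, 2L, function(col) table(factor(col, levels = BASES)))
  probs <- (cnt + pseudocount) / (n + 4 * pseudocount)
  flank <- wlen / 2L
  dimnames(probs) <- list(BASES,
                          c(paste0(-(flank:1)), paste0("+", 1:flank)))
  methods::new("PWM", probs = probs, pseudocount = pseudocount,
               nWindows = as.integer(n), sbsClass = sbsClass,
               platform = platform)
}

#' Log-likelihood ratio of windows under two PWMs
#'
#' Sum over positions of the natural log ratio of the two PWMs'
#' probabilities for the observed base: positive scores favour the first
#' (two-color platform) PWM.
#'
#' @param windows character vector of windows (NAs pass through as NA).
#' @param pwmNova,pwmHiseq [PWM-class] objects sharing class and frame.
#' @return Numeric vector of log-likelihood ratios.
#' @export
logLR <- function(windows, pwmNova, pwmHiseq) {
  stopifnot(methods::is(pwmNova, "PWM"), methods::is(pwmHiseq, "PWM"))
  lp <- log(pwmProbs(pwmNova)) - log(pwmProbs(pwmHiseq))
  npos <- ncol(lp)
  out <- rep(NA_real_, length(windows))
  ok <- !is.na(windows)
  if (!any(ok)) return(out)
  if (any(nchar(windows[ok]) != npos)) {
    stop("window length does not match the PWMs", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(windows[ok], ""))
  idx <- matrix(match(mat, BASES), nrow = nrow(mat))
  scores <- vapply(seq_len(nrow(idx)), function(i) {
    sum(lp[cbind(idx[i, ], seq_len(npos))])
  }, numeric(1))
  out[ok] <- scores
  out
}

#' Exact null distribution of the PWM log-likelihood ratio
#'
#' The distribution of [logLR()] when the window is drawn
#' position-independently from the background (four-color platform) PWM:
#' the per-position 4-outcome log-ratio distributions are convolved
#' exactly, and atoms closer than 1e-12 are merged. For the default
#' 8-position window this is at most 4^8 = 65,536 atoms.
#'
#' @param pwmNova,pwmHiseq [PWM-class] objects sharing the frame.
#' @return An [LRNull-class].
#' @export
lrNull <- function(pwmNova, pwmHiseq) {
  stopifnot(methods::is(pwmNova, "PWM"), methods::is(pwmHiseq, "PWM"))
  lp <- log(pwmProbs(pwmNova)) - log(pwmProbs(pwmHiseq))
  ph <- pwmProbs(pwmHiseq)
  value <- 0
  prob <- 1
  for (j in seq_len(ncol(lp))) {
    value <- outer(value, lp[, j], "+")
    prob <- outer(prob, ph[, j], "*")
    key <- round(value, 12L)
    agg <- rowsum(as.vector(prob), group = as.vector(key))
    value <- as.numeric(rownames(agg))
    prob <- as.vector(agg)
    ord <- order(value)
    value <- value[ord]
    prob <- prob[ord]
  }
  methods::new("LRNull", value = value, prob = prob)
}

# P(null >= q), inclusive of ties at q (conservative); vectorised.
#' @noRd
.nullSurvival <- function(null, q) {
  revCum <- rev(cumsum(rev(null@prob)))  # P(X >= value[i])
  # first atom with value >= q - tol
  idx <- findInterval(q - 1e-9, null@value) + 1L
  out <- ifelse(idx > length(null@value), 0, revCum[pmin(idx,
                                                         length(null@value))])
  as.numeric(out)
}

#' Classify calls as artifacts by PWM likelihood ratio
#'
#' Scores each call's window with [logLR()] and computes a one-sided
#' p-value P(null >= score) under the exact background null; calls with
#' p < alpha are flagged as artifacts. Calls whose window cannot be
#' extracted pass through unflagged with status "unevaluated".
#'
#' @param calls variant-call data.frame.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param pwmNova,pwmHiseq the two platform PWMs.
#' @param null the [LRNull-class] from [lrNull()]; computed on the fly
#'   when NULL.
#' @param alpha significance level (default 0.05).
#' @param orient window orientation, see [extractWindow()].
#' @return The call table with added columns window, loglr, pValue,
#'   artifact, status.
#' @export
classifyCalls <- function(calls, genome, pwmNova, pwmHiseq, null = NULL,
                          alpha = 0.05, orient = "pyrimidine") {
  .checkCalls(calls, requireDepth = FALSE)
  if (is.null(null)) null <- lrNull(pwmNova, pwmHiseq)
  flank <- ncol(pwmProbs(pwmNova)) / 2L
  win <- .extractWindows(genome, calls, flank = flank, orient = orient)
  score <- logLR(win, pwmNova, pwmHiseq)
  pv <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  pv[ok] <- .nullSurvival(null, score[ok])
  calls$window <- win
  calls$loglr <- score
  calls$pValue <- pv
  calls$artifact <- !is.na(pv) & pv < alpha
  calls$status <- ifelse(ok, "evaluated", "unevaluated")
  calls
}

#' Correct a callset with per-class PWM likelihood-ratio filters
#'
#' For each substitution class in `classes`, builds one PWM per platform
#' from the training callsets' windows, derives the exact null under the
#' four-color-platform PWM, classifies every call of that class, and
#' removes flagged calls from the kept set. Classes with an empty
#' training set on either platform are skipped with a warning and their
#' calls pass through. The training and test callsets may coincide; no
#' cross-validation split is imposed.
#'
#' @param calls callset to correct.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param trainingNova,trainingHiseq training callsets for the two-color
#'   and four-color platform PWMs.
#' @param alpha per-call significance level.
#' @param classes substitution classes to filter (default all six).
#' @param pseudocount,flank PWM training parameters.
#' @return A list: `kept` and `flagged` call tables (flagged calls carry
#'   `TG_ARTIFACT = TRUE` for [writeVariants()]), `summary` (per-class
#'   before/after counts and fold change), and `pwms` (per-class list of
#'   nova/hiseq PWMs).
#' @export
correctCallset <- function(calls, genome, trainingNova, trainingHiseq,
                           alpha = 0.05, classes = SBS_CLASSES,
                           pseudocount = 1, flank = 4L) {
  .checkCalls(calls, requireDepth = FALSE)
  stopifnot(all(classes %in% SBS_CLASSES))
  if (nrow(calls) == 0L) {
    return(list(kept = calls, flagged = calls[0, , drop = FALSE],
                summary = data.frame(), pwms = list()))
  }
  callClass <- collapseSBS(calls$ref, calls$alt)
  trainNovaClass <- if (nrow(trainingNova)) {
    collapseSBS(trainingNova$ref, trainingNova$alt)
  } else character(0)
  trainHiseqClass <- if (nrow(trainingHiseq)) {
    collapseSBS(trainingHiseq$ref, trainingHiseq$alt)
  } else character(0)
  calls$artifact <- FALSE
  calls$pValue <- NA_real_
  calls$loglr <- NA_real_
  calls$status <- "unevaluated"
  pwms <- list()
  for (cl in classes) {
    inClass <- callClass == cl
    if (!any(inClass)) next
    wNova <- .extractWindows(genome,
                             trainingNova[trainNovaClass == cl, ,
                                          drop = FALSE], flank = flank)
    wHiseq <- .extractWindows(genome,
                              trainingHiseq[trainHiseqClass == cl, ,
                                            drop = FALSE], flank = flank)
    if (sum(!is.na(wNova)) == 0L || sum(!is.na(wHiseq)) == 0L) {
      warning("class ", cl, " has an empty training set; calls pass through",
              call. = FALSE)
      next
    }
    pwmN <- buildPWM(wNova, pseudocount = pseudocount, sbsClass = cl,
                     platform = "NovaSeq")
    pwmH <- buildPWM(wHiseq, pseudocount = pseudocount, sbsClass = cl,
                     platform = "HiSeq")
    null <- lrNull(pwmN, pwmH)
    res <- classifyCalls(calls[inClass, , drop = FALSE], genome,
                         pwmN, pwmH, null = null, alpha = alpha)
    calls$artifact[inClass] <- res$artifact
    calls$pValue[inClass] <- res$pValue
    calls$loglr[inClass] <- res$loglr
    calls$status[inClass] <- res$status
    pwms[[cl]] <- list(nova = pwmN, hiseq = pwmH)
  }
  kept <- calls[!calls$artifact, , drop = FALSE]
  flagged <- calls[calls$artifact, , drop = FALSE]
  if (nrow(flagged)) flagged$TG_ARTIFACT <- TRUE
  summary <- do.call(rbind, lapply(SBS_CLASSES, function(cl) {
    before <- sum(callClass == cl)
    removed <- sum(callClass == cl & calls$artifact)
    after <- before - removed
    data.frame(class = cl, nBefore = before, nFlagged = removed,
               nKept = after,
               foldChange = if (after > 0) before / after else
                 ifelse(before > 0, Inf, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(kept) <- rownames(flagged) <- rownames(summary) <- NULL
  list(kept = kept, flagged = flagged, summary = summary, pwms = pwms)
}

#' Serialise PWMs to a JSON sidecar
#'
#' Writes per-class PWM pairs (probabilities plus provenance: training
#' size, pseudocount, frame) as JSON; [readPWMs()] restores them.
#'
#' @param pwms the `pwms` element of a [correctCallset()] result.
#' @param path output JSON path.
#' @export
writePWMs <- function(pwms, path) {
  ser <- lapply(pwms, function(pair) {
    lapply(pair, function(p) {
      list(probs = pwmProbs(p), pseudocount = p@pseudocount,
           nWindows = nWindows(p), sbsClass = sbsClass(p),
           platform = platform(p), frame = "pyrimidine")
    })
  })
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePWMs
#' @param path JSON path written by `writePWMs`.
#' @export
readPWMs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(pair) {
    lapply(pair, function(p) {
      probs <- as.matrix(p$probs)
      rownames(probs) <- BASES
      flank <- ncol(probs) / 2L
      colnames(probs) <- c(paste0(-(flank:1)), paste0("+", 1:flank))
      methods::new("PWM", probs = probs, pseudocount = p$pseudocount,
                   nWindows = as.integer(p$nWindows),
                   sbsClass = p$sbsClass, platform = p$platform)
    })
  })
}
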