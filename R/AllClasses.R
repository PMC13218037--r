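#' ADMatrix: mismatch-site counts by substitution class and allele depth
#'
#' Counts of mismatched sites indexed by collapsed single-base-substitution
#' class (rows, the six pyrimidine-referenced classes) and alternate allele
#' depth bin (columns, 1..adMax; depths above adMax accumulate in the top
#' bin). One matrix per sequencing platform.
#'
#' @slot counts integer matrix, 6 x adMax, rows named by [SBS_CLASSES].
#' @slot platform single character label, e.g. "NovaSeq".
#'
#' @seealso [adSpectrum()] which builds one from a pileup-mismatch table,
#'   [perADEnrichment()] which compares two.
#' @export
setClass("ADMatrix",
  representation(counts = "matrix", platform = "character")
)

setValidity("ADMatrix", function(object) {
  msg <- character(0)
  cnt <- object@counts
  if (!identical(rownames(cnt), SBS_CLASSES)) {
    msg <- c(msg, "counts rows must be the six SBS classes in COSMIC order")
  }
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(object@platform) != 1L) {
    msg <- c(msg, "platform must be a single label")
  }
  if (length(msg)) msg else TRUE
})

#' PWM: position weight matrix over flanking bases of a substitution class
#'
#' Per-position base probabilities learned from fixed-width windows around
#' variant positions (the variant base itself is excluded), in the
#' pyrimidine frame. Columns are flank offsets -flank..-1, +1..+flank.
#'
#' @slot probs numeric matrix, 4 x 2*flank; rows A,C,G,T; columns sum to 1.
#' @slot pseudocount the Laplace pseudocount used during training.
#' @slot nWindows number of training windows.
#' @slot sbsClass the substitution class the PWM was trained on.
#' @slot platform platform label of the training callset.
#'
#' @seealso [buildPWM()], [logLR()], [lrNull()].
#' @export
setClass("PWM",
  representation(probs = "matrix", pseudocount = "numeric",
                 nWindows = "integer", sbsClass = "character",
                 platform = "character")
)

setValidity("PWM", function(object) {
  msg <- character(0)
  p <- object@probs
  if (!identical(rownames(p), BASES)) {
    msg <- c(msg, "probs rows must be A,C,G,T")
  }
  if (any(p <= 0)) {
    msg <- c(msg, "all probabilities must be > 0 (pseudocount guarantees this)")
  }
  if (ncol(p) %% 2L != 0L) {
    msg <- c(msg, "probs must have an even number of flank columns")
  }
  if (any(abs(colSums(p) - 1) > 1e-9)) {
    msg <- c(msg, "each column must sum to 1 (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' LRNull: exact null distribution of a PWM log-likelihood ratio
#'
#' The exact distribution of the log-likelihood ratio score of a window
#' drawn position-independently from the background (four-color platform)
#' PWM. Atoms are stored sorted ascending; ties in the score are merged.
#'
#' @slot value numeric, distinct log-LR values in ascending order.
#' @slot prob probabilities, summing to 1 within 1e-9.
#'
#' @seealso [lrNull()], [classifyCalls()].
#' @export
setClass("LRNull", representation(value = "numeric", prob = "numeric"))

setValidity("LRNull", function(object) {
  msg <- character(0)
  if (length(object@value) != length(object@prob)) {
    msg <- c(msg, "value and prob must have equal length")
  }
  if (is.unsorted(object@value, strictly = TRUE)) {
    msg <- c(msg, "values must be strictly ascending (merged atoms)")
  }
  if (abs(sum(object@prob) - 1) > 1e-9) {
    msg <- c(msg, "probabilities must sum to 1 (within 1e-9)")
  }
  if (any(object@prob < 0)) msg <- c(msg, "probabilities must be >= 0")
  if (length(msg)) msg else TRUE
})
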