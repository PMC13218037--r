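#' @importFrom BiocGenerics counts
NULL

#' Accessors for duochromeQC S4 objects
#'
#' `counts()` returns the class-by-AD count matrix of an [ADMatrix-class];
#' `platform()` the platform label; `adMax()` the top AD bin;
#' `pwmProbs()` the 4 x 2*flank probability matrix of a [PWM-class];
#' `nWindows()` its training size; `sbsClass()` its substitution class;
#' `nullAtoms()` the (value, prob) atom table of an [LRNull-class].
#'
#' @param object an object of the documented class.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("platform", function(object) standardGeneric("platform"))

#' @rdname accessors
#' @export
setGeneric("adMax", function(object) standardGeneric("adMax"))

#' @rdname accessors
#' @export
setGeneric("pwmProbs", function(object) standardGeneric("pwmProbs"))

#' @rdname accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))

#' @rdname accessors
#' @export
setGeneric("sbsClass", function(object) standardGeneric("sbsClass"))

#' @rdname accessors
#' @export
setGeneric("nullAtoms", function(object) standardGeneric("nullAtoms"))

#' @rdname accessors
#' @export
setMethod("counts", "ADMatrix", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("platform", "ADMatrix", function(object) object@platform)

#' @rdname accessors
#' @export
setMethod("platform", "PWM", function(object) object@platform)

#' @rdname accessors
#' @export
setMethod("adMax", "ADMatrix", function(object) ncol(object@counts))

#' @rdname accessors
#' @export
setMethod("pwmProbs", "PWM", function(object) object@probs)

#' @rdname accessors
#' @export
setMethod("nWindows", "PWM", function(object) object@nWindows)

#' @rdname accessors
#' @export
setMethod("sbsClass", "PWM", function(object) object@sbsClass)

#' @rdname accessors
#' @export
setMethod("nullAtoms", "LRNull", function(object) {
  data.frame(value = object@value, prob = object@prob)
})

setMethod("show", "ADMatrix", function(object) {
  cat("ADMatrix for platform '", object@platform, "' (",
      nrow(object@counts), " SBS classes x AD 1..", ncol(object@counts),
      ")\n", sep = "")
  cat("  total mismatch sites:", sum(object@counts), "\n")
  shown <- min(6L, ncol(object@counts))
  print(object@counts[, seq_len(shown), drop = FALSE])
  if (ncol(object@counts) > shown) {
    cat("  ... (", ncol(object@counts) - shown, " more AD bins)\n", sep = "")
  }
})

setMethod("show", "PWM", function(object) {
  cat("PWM (", object@sbsClass, ", platform '", object@platform,
      "'): ", ncol(object@probs), " flank positions, trained on ",
      object@nWindows, " windows (pseudocount ", object@pseudocount,
      ")\n", sep = "")
  print(round(object@probs, 3))
})

setMethod("show", "LRNull", function(object) {
  cat("Exact log-LR null distribution: ", length(object@value),
      " atoms, support [", round(min(object@value), 3), ", ",
      round(max(object@value), 3), "]\n", sep = "")
})
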