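# Pooled two-proportion z-tests of platform-wise mismatch proportions,
# per-allele-depth enrichment tables, and FDR control.

#' Pooled two-proportion z-test
#'
#' Tests the difference between two proportions x1/n1 and x2/n2 with the
#' pooled-variance z statistic
#' \deqn{z = (p_1 - p_2) / \sqrt{p(1-p)(1/n_1 + 1/n_2)}}
#' where \eqn{p} is the pooled proportion \eqn{(x_1+x_2)/(n_1+n_2)}, and a
#' two-sided p-value from the standard normal. No continuity correction is
#' applied. Degenerate pooled proportions (0 or 1) give z = 0, p = 1.
#'
#' @param x1,n1 successes and trials in the first group (e.g. T>G
#'   mismatches and all mismatches on the two-color platform).
#' @param x2,n2 the same for the second group.
#' @return A list with p1, p2, pPooled, n1, n2, z, pValue.
#' @examples
#' twoProportionZ(30, 100, 20, 100)$z  # about 1.633
#' @export
twoProportionZ <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("need 0 <= x <= n in both groups", call. = FALSE)
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    z <- 0
    pv <- 1
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    pv <- 2 * stats::pnorm(-abs(z))
  }
  list(p1 = p1, p2 = p2, pPooled = pp, n1 = n1, n2 = n2,
       z = z, pValue = pv)
}

#' Difference between two proportions
#'
#' Convenience for the enrichment plots: a value greater than 0 indicates
#' an excess in the first (two-color) platform.
#'
#' @param p1,p2 proportions in \[0, 1\].
#' @return `p1 - p2`.
#' @export
proportionDifference <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  p1 - p2
}

#' q-values with FDR control
#'
#' Converts p-values to q-values and flags significance at `q < alpha`.
#' The default is Benjamini-Hochberg step-up adjustment (deterministic,
#' parameter-free); `method = "storey"` additionally scales by the Storey
#' null-proportion estimate \eqn{\hat\pi_0 = \min(1, \#\{p > 0.5\} /
#' (0.5 m))}.
#'
#' @param pValues numeric vector in \[0, 1\].
#' @param method "BH" (default) or "storey".
#' @param alpha FDR level for the significance flags.
#' @return A list with `q` (same order as the input) and `significant`
#'   (logical flags, `q < alpha`).
#' @export
fdrQvalues <- function(pValues, method = c("BH", "storey"), alpha = 0.05) {
  method <- match.arg(method)
  if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(pValues, method = "BH")
  if (method == "storey" && length(pValues)) {
    pi0 <- min(1, sum(pValues > 0.5) / (0.5 * length(pValues)))
    pi0 <- max(pi0, 1 / length(pValues))  # avoid a degenerate zero
    q <- pmin(1, pi0 * q)
  }
  list(q = q, significant = q < alpha)
}

#' Per-allele-depth platform enrichment table
#'
#' For each AD stratum, tests whether the proportion of mismatch sites
#' (or calls) belonging to `class` differs between the two platforms,
#' using [twoProportionZ()] with x = the class count and n = all sites at
#' that AD. q-values are computed jointly across the AD strata of this
#' comparison (the per-sample multiple-testing family). The AD = 1 row is
#' computed but flagged `disregarded`: single-read support mostly
#' reflects residual random sequencing/alignment error, not the
#' platform artifact, and is never counted as significant.
#'
#' @param nova [ADMatrix-class] for the two-color (NovaSeq-type) platform.
#' @param hiseq [ADMatrix-class] for the four-color platform; must share
#'   `adMax` with `nova`.
#' @param class substitution class to test (default "T>G").
#' @param adRange AD strata to test (default 1..adMax).
#' @param alpha FDR level.
#' @param fdrMethod passed to [fdrQvalues()].
#' @return A data.frame with one row per AD: counts, proportions, z,
#'   pValue, qValue, status ("ok", "disregarded" or "untestable"), and
#'   `significant` (q < alpha, ok rows only).
#' @export
perADEnrichment <- function(nova, hiseq, class = "T>G", adRange = NULL,
                            alpha = 0.05, fdrMethod = "BH") {
  stopifnot(methods::is(nova, "ADMatrix"), methods::is(hiseq, "ADMatrix"))
  if (adMax(nova) != adMax(hiseq)) {
    stop("the two ADMatrix objects must share adMax", call. = FALSE)
  }
  if (!class %in% SBS_CLASSES) stop("unknown SBS class: ", class,
                                    call. = FALSE)
  if (is.null(adRange)) adRange <- seq_len(adMax(nova))
  cn <- counts(nova)
  ch <- counts(hiseq)
  x1 <- cn[class, adRange]
  n1 <- colSums(cn)[adRange]
  x2 <- ch[class, adRange]
  n2 <- colSums(ch)[adRange]
  testable <- n1 > 0 & n2 > 0
  z <- pv <- p1 <- p2 <- ppool <- rep(NA_real_, length(adRange))
  for (i in which(testable)) {
    t <- twoProportionZ(x1[i], n1[i], x2[i], n2[i])
    z[i] <- t$z; pv[i] <- t$pValue
    p1[i] <- t$p1; p2[i] <- t$p2; ppool[i] <- t$pPooled
  }
  q <- rep(NA_real_, length(adRange))
  if (any(testable)) q[testable] <- fdrQvalues(pv[testable],
                                               method = fdrMethod)$q
  status <- ifelse(!testable, "untestable",
                   ifelse(adRange == 1L, "disregarded", "ok"))
  out <- data.frame(
    ad = adRange, class = class,
    xNova = as.integer(x1), nNova = as.integer(n1),
    xHiseq = as.integer(x2), nHiseq = as.integer(n2),
    pNova = p1, pHiseq = p2, pPooled = ppool,
    propDiff = p1 - p2,
    z = z, pValue = pv, qValue = q,
    status = status,
    significant = !is.na(q) & q < alpha & status == "ok",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
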