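test_that("window extraction concatenates flanks and flips purine calls", {
  g <- smallGenome(c(c1 = "AACCTGGTT"))
  w <- extractWindow(g, oneCall("c1", 5, "T", "G"))
  expect_equal(as.character(w), "AACCGGTT")
  # purine-referenced call: the window is the reverse complement's flanks
  g2 <- smallGenome(c(c1 = "TTGGAACCA"))
  w2 <- extractWindow(g2, oneCall("c1", 5, "A", "C"))
  expect_equal(as.character(w2), "TGGTCCAA")
  # too close to the contig start: excluded with a counter
  w3 <- extractWindow(g, oneCall("c1", 2, "A", "C"))
  expect_true(is.na(w3[1]))
  expect_equal(attr(w3, "excluded"), 1L)
})

test_that("PWM training applies the Laplace pseudocount per column", {
  p <- buildPWM("ACGTACGT", pseudocount = 1)
  probs <- pwmProbs(p)
  expect_equal(dim(probs), c(4L, 8L))
  expect_true(all(abs(colSums(probs) - 1) < 1e-12))
  # single window: observed base (1+1)/(1+4) = 0.4, others 0.2
  expect_equal(probs["A", "-4"], 0.4)
  expect_equal(probs["C", "-4"], 0.2)
  expect_equal(probs["C", "-3"], 0.4)
  expect_equal(nWindows(p), 1L)
  expect_error(buildPWM(character(0)), "training")

  # law of large numbers: i.i.d. uniform windows converge to 0.25
  set.seed(43)
  win <- vapply(1:20000, function(i) {
    paste(sample(BASES4, 8, replace = TRUE), collapse = "")
  }, character(1))
  pU <- buildPWM(win)
  expect_true(all(abs(pwmProbs(pU) - 0.25) < 0.015))
})

test_that("log-likelihood ratios cancel identical columns and antisymmetrise", {
  set.seed(47)
  win <- vapply(1:50, function(i) {
    paste(sample(BASES4, 8, replace = TRUE), collapse = "")
  }, character(1))
  pA <- buildPWM(win)
  expect_equal(logLR("ACGTACGT", pA, pA), 0)
  # perturb one column only: the log-ratio reduces to that column's term
  pB <- pA
  probsB <- pwmProbs(pB)
  probsB[, 3] <- c(0.55, 0.15, 0.15, 0.15)
  pB <- methods::new("PWM", probs = probsB, pseudocount = 1,
                     nWindows = 50L, sbsClass = NA_character_,
                     platform = NA_character_)
  w <- "GGAGGGGG"  # column 3 holds A
  expect_equal(logLR(w, pB, pA),
               log(0.55 / pwmProbs(pA)["A", 3]), tolerance = 1e-12)
  expect_equal(logLR(w, pA, pB), -logLR(w, pB, pA))
})

test_that("the exact null equals brute-force enumeration (flank 2 and 4)", {
  set.seed(53)
  for (flank in c(2L, 4L)) {
    wlen <- 2L * flank
    winN <- vapply(1:40, function(i) {
      paste(sample(BASES4, wlen, replace = TRUE, prob = c(1, 2, 3, 4)),
            collapse = "")
    }, character(1))
    winH <- vapply(1:40, function(i) {
      paste(sample(BASES4, wlen, replace = TRUE), collapse = "")
    }, character(1))
    pN <- buildPWM(winN)
    pH <- buildPWM(winH)
    null <- lrNull(pN, pH)
    atoms <- nullAtoms(null)
    expect_lt(abs(sum(atoms$prob) - 1), 1e-9)
    brute <- naiveNull(pN, pH)
    # compare survival functions at the brute-force support
    qs <- quantile(brute$value, c(0.05, 0.25, 0.5, 0.75, 0.95))
    for (q in qs) {
      sBrute <- sum(brute$prob[brute$value >= q - 1e-9])
      idx <- atoms$value >= q - 1e-9
      expect_equal(sum(atoms$prob[idx]), sBrute, tolerance = 1e-9)
    }
    # means agree too
    expect_equal(sum(atoms$value * atoms$prob),
                 sum(brute$value * brute$prob), tolerance = 1e-9)
  }
})

test_that("identical PWMs give a point-mass null, p = 1 and no flags", {
  set.seed(59)
  win <- vapply(1:30, function(i) {
    paste(sample(BASES4, 8, replace = TRUE), collapse = "")
  }, character(1))
  p <- buildPWM(win)
  null <- lrNull(p, p)
  atoms <- nullAtoms(null)
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$value, 0)
  genome <- simulateReference(5000, 0.5)
  calls <- simulateTrueMutations(genome, 50)
  res <- classifyCalls(calls, genome, p, p, null = null)
  expect_true(all(res$pValue[res$status == "evaluated"] == 1))
  expect_false(any(res$artifact))
  # alpha = 0 flags nothing even under different PWMs
  win2 <- vapply(1:30, function(i) {
    paste(sample(BASES4, 8, replace = TRUE, prob = c(4, 1, 1, 4)),
          collapse = "")
  }, character(1))
  p2 <- buildPWM(win2)
  res0 <- classifyCalls(calls, genome, p2, p, alpha = 0)
  expect_false(any(res0$artifact))
})

test_that("null survival is monte-carlo consistent and p is monotone in the score", {
  set.seed(61)
  winN <- vapply(1:60, function(i) {
    paste(sample(BASES4, 8, replace = TRUE, prob = c(1, 3, 3, 1)),
          collapse = "")
  }, character(1))
  winH <- vapply(1:60, function(i) {
    paste(sample(BASES4, 8, replace = TRUE), collapse = "")
  }, character(1))
  pN <- buildPWM(winN); pH <- buildPWM(winH)
  null <- lrNull(pN, pH)
  atoms <- nullAtoms(null)
  # MC draws from the background PWM
  nMC <- 200000L
  ph <- pwmProbs(pH)
  lp <- log(pwmProbs(pN)) - log(ph)
  draws <- matrix(0, nMC, 8)
  for (j in 1:8) {
    draws[, j] <- sample(lp[, j], nMC, replace = TRUE, prob = ph[, j])
  }
  score <- rowSums(draws)
  for (q in quantile(atoms$value, c(0.1, 0.3, 0.5, 0.7, 0.9))) {
    exact <- sum(atoms$prob[atoms$value >= q - 1e-9])
    mc <- mean(score >= q - 1e-9)
    se <- sqrt(exact * (1 - exact) / nMC)
    expect_lt(abs(mc - exact), 3 * se + 1e-9)
  }
  # monotonicity: larger observed score never gives larger p
  qs <- sort(runif(20, min(atoms$value), max(atoms$value)))
  surv <- vapply(qs, function(q) {
    sum(atoms$prob[atoms$value >= q - 1e-9])
  }, numeric(1))
  expect_true(all(diff(surv) <= 1e-12))
})

test_that("callset correction is alpha-calibrated under a shared context model", {
  set.seed(67)
  flagged <- total <- 0
  for (i in 1:20) {
    genome <- simulateReference(40000, 0.42)
    trainN <- simulateTrueMutations(genome, 1200)
    trainH <- simulateTrueMutations(genome, 1200)
    test <- simulateTrueMutations(genome, 300)
    out <- suppressWarnings(
      correctCallset(test, genome, trainN, trainH, alpha = 0.05))
    ev <- out$kept$status == "evaluated"
    flagged <- flagged + nrow(out$flagged)
    total <- total + sum(ev) + nrow(out$flagged)
  }
  # both platforms' PWMs learned from the same context distribution:
  # the flag rate tracks alpha (finite training inflates it modestly)
  expect_lt(flagged / total, 0.10)
  expect_gt(flagged / total, 0.01)

  # classes outside the requested set are never flagged
  genome <- simulateReference(20000, 0.42)
  calls <- simulateTrueMutations(genome, 300)
  out2 <- suppressWarnings(
    correctCallset(calls, genome, calls, calls, classes = "T>G"))
  cls <- collapseSBS(out2$flagged$ref, out2$flagged$alt)
  expect_true(all(cls == "T>G") || nrow(out2$flagged) == 0L)

  # empty input: empty outputs
  out3 <- correctCallset(calls[0, ], genome, calls, calls)
  expect_equal(nrow(out3$kept), 0L)
  expect_equal(nrow(out3$flagged), 0L)
})

test_that("PWM JSON sidecars round-trip probabilities and provenance", {
  set.seed(71)
  win <- vapply(1:25, function(i) {
    paste(sample(BASES4, 8, replace = TRUE), collapse = "")
  }, character(1))
  pwms <- list("T>G" = list(nova = buildPWM(win, sbsClass = "T>G",
                                            platform = "NovaSeq"),
                            hiseq = buildPWM(rev(win), sbsClass = "T>G",
                                             platform = "HiSeq")))
  f <- withr::local_tempfile(fileext = ".json")
  writePWMs(pwms, f)
  back <- readPWMs(f)
  expect_equal(pwmProbs(back[["T>G"]]$nova), pwmProbs(pwms[["T>G"]]$nova),
               tolerance = 1e-12)
  expect_equal(nWindows(back[["T>G"]]$hiseq), 25L)
  expect_equal(platform(back[["T>G"]]$nova), "NovaSeq")
})
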