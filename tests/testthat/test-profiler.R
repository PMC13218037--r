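test_that("SBS collapsing sends all 12 ordered pairs to 6 classes, twice each", {
  expect_equal(collapseSBS("A", "C"), "T>G")
  expect_equal(collapseSBS("C", "T"), "C>T")
  pairs <- expand.grid(ref = BASES4, alt = BASES4,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- collapseSBS(pairs$ref, pairs$alt)
  expect_equal(sort(unique(cls)), sort(SBS_CLASSES))
  expect_true(all(table(cls) == 2L))
  expect_error(collapseSBS("A", "A"), "differ")
  expect_error(collapseSBS("N", "A"), "A/C/G/T")
})

test_that("pileup counting matches a per-column brute-force oracle", {
  set.seed(3)
  for (rep in 1:8) {
    contigSeq <- paste(sample(BASES4, 60, replace = TRUE), collapse = "")
    genome <- smallGenome(c(c1 = contigSeq))
    reads <- randomReads(contigSeq, nReads = 10L, readLen = 20L,
                         mutRate = 0.15)
    got <- pileupMismatches(reads, genome, platform = "p")$mismatches
    want <- naivePileup(reads, contigSeq)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$pos, want$alt), ]
      expect_equal(got$pos, want$pos)
      expect_equal(got$ref, want$ref)
      expect_equal(got$alt, want$alt)
      expect_equal(got$ad, want$ad)
      expect_equal(got$dp, want$dp)
    }
  }
})

test_that("reference-identical reads produce no mismatches; shared dp across alts", {
  contigSeq <- strrep("ACGT", 15)
  genome <- smallGenome(c(c1 = contigSeq))
  reads <- randomReads(contigSeq, nReads = 5L, readLen = 20L, mutRate = 0)
  expect_equal(nrow(pileupMismatches(reads, genome)$mismatches), 0L)

  # two distinct alts at one site share the column depth
  reads$pos <- rep(11L, 5)
  b <- strsplit(substr(contigSeq, 11, 30), "")[[1]]
  ref <- b[5]  # position 15
  alts <- setdiff(BASES4, ref)
  mk <- function(alt) { bb <- b; bb[5] <- alt; paste(bb, collapse = "") }
  reads$bases <- c(mk(alts[1]), mk(alts[1]), mk(alts[2]),
                   paste(b, collapse = ""), paste(b, collapse = ""))
  mm <- pileupMismatches(reads, genome)$mismatches
  at15 <- mm[mm$pos == 15L, ]
  expect_equal(nrow(at15), 2L)
  expect_equal(sort(at15$ad), c(1L, 2L))
  expect_equal(unique(at15$dp), 5L)
})

test_that("reads beyond the contig end raise an error naming the read", {
  genome <- smallGenome(c(c1 = strrep("A", 30)))
  reads <- randomReads(strrep("A", 30), nReads = 1L, readLen = 20L,
                       mutRate = 0)
  reads$pos <- 25L
  expect_error(pileupMismatches(reads, genome), "r001")
})

test_that("platform-specific sites require absence with coverage on the other platform", {
  a <- rbind(oneCall("c1", 10, "T", "G", 6, 30),   # mismatch only in a
             oneCall("c1", 20, "C", "A", 3, 30),   # mismatched in both
             oneCall("c1", 40, "T", "A", 2, 30))   # uncovered in b
  b <- oneCall("c1", 20, "C", "A", 5, 25)
  covB <- data.frame(contig = "c1", pos = c(10L, 20L), dp = c(30L, 25L))
  out <- platformSpecificSites(a, b, covB)
  expect_equal(out$pos, 10L)
  # same position, different alt counts as specific
  b2 <- oneCall("c1", 10, "T", "A", 2, 30)
  out2 <- platformSpecificSites(a[1, ], b2, covB)
  expect_equal(out2$pos, 10L)
  # with minOtherDepth = 0 no coverage map is needed
  out3 <- platformSpecificSites(a, b, minOtherDepth = 0L)
  expect_equal(out3$pos, c(10L, 40L))
})

test_that("AD spectra conserve counts and cap at the top bin", {
  sites <- rbind(oneCall("c1", 1, "T", "G", 2, 30),
                 oneCall("c1", 2, "T", "G", 2, 30),
                 oneCall("c1", 3, "T", "G", 2, 30),
                 oneCall("c1", 4, "C", "T", 40, 60))
  m <- adSpectrum(sites, adMax = 25L)
  expect_s4_class(m, "ADMatrix")
  expect_equal(counts(m)["T>G", "2"], 3L)
  expect_equal(counts(m)["C>T", "25"], 1L)  # ad 40 capped into the top bin
  expect_equal(sum(counts(m)), nrow(sites))
  # order independence
  m2 <- adSpectrum(sites[sample(nrow(sites)), ], adMax = 25L)
  expect_equal(counts(m2), counts(m))
})

test_that("T>G fraction behaves at the documented fixtures", {
  cnt <- matrix(0L, 6, 6, dimnames = list(SBS_CLASSES, 1:6))
  cnt[, 3] <- c(9L, 9L, 9L, 8L, 8L, 57L)  # 57 of 100 are T>G
  m <- methods::new("ADMatrix", counts = cnt, platform = "nova")
  expect_equal(tgFraction(m, 3), 0.57)
  cnt2 <- matrix(1L, 6, 6, dimnames = list(SBS_CLASSES, 1:6))
  m2 <- methods::new("ADMatrix", counts = cnt2, platform = "x")
  expect_equal(tgFraction(m2, 2), 1 / 6)
  cnt3 <- matrix(0L, 6, 6, dimnames = list(SBS_CLASSES, 1:6))
  cnt3["T>G", 4] <- 5L
  m3 <- methods::new("ADMatrix", counts = cnt3, platform = "x")
  expect_equal(tgFraction(m3, 4), 1)
  expect_true(is.na(tgFraction(m3, 2)))  # empty stratum: undefined, not 0
})

test_that("allele fractions derive from AD/DP with guarded inputs", {
  expect_equal(afFromAD(2, 47), 2 / 47, tolerance = 1e-15)
  expect_equal(round(100 * afFromAD(2, 47), 2), 4.26)
  expect_equal(afFromAD(0, 30), 0)
  expect_equal(afFromAD(47, 47), 1)
  expect_error(afFromAD(1, 0), "positive")
  expect_error(afFromAD(5, 3), "0 <= ad <= dp")
})

test_that("AD recalculation from pileups enforces the alt-AD >= 2 rule", {
  contigSeq <- strrep("ACGT", 25)
  genome <- smallGenome(c(c1 = contigSeq))
  reads <- randomReads(contigSeq, nReads = 6L, readLen = 100L, mutRate = 0)
  reads$pos <- rep(1L, 6)
  # plant alt support: 2 reads with G at position 13 (ref A), 1 read with
  # T at position 26 (ref C)
  plant <- function(readIdx, pos, alt) {
    for (i in readIdx) {
      b <- strsplit(reads$bases[i], "")[[1]]
      b[pos] <- alt
      reads$bases[i] <<- paste(b, collapse = "")
    }
  }
  plant(1:2, 13L, "G")
  plant(3L, 26L, "T")
  calls <- rbind(oneCall("c1", 13, "A", "G", 5, 50),
                 oneCall("c1", 26, "C", "T", 5, 50))
  out <- recalculateAD(calls, reads, genome)
  expect_equal(nrow(out$calls), 1L)
  expect_equal(out$calls$pos, 13L)
  expect_equal(out$calls$ad, 2L)
  expect_equal(out$calls$dp, 6L)
  expect_equal(out$dropped, 1L)
  # empty alignment stream drops everything with a warning
  expect_warning(res <- recalculateAD(calls, reads[0, ], genome),
                 "empty alignment")
  expect_equal(nrow(res$calls), 0L)
  expect_equal(res$dropped, 2L)
})

test_that("coverage downsampling is binomial thinning with expected linear scaling", {
  sites <- do.call(rbind, lapply(1:200, function(i) {
    oneCall("c1", i, "T", "G", 6L, 30L)
  }))
  # p = 1 is the identity
  expect_equal(downsampleSites(sites, 30, 30, seed = 1), sites)
  expect_error(downsampleSites(sites, 30, 40), "targetCov")
  # thinned ad has Binomial(6, 1/2) mean; average over many sites
  set.seed(5)
  thinned <- downsampleSites(sites, 30, 15)
  # E[ad | ad > 0] = 3 / (1 - 2^-6); 200 sites give ~0.1 precision
  condMean <- 3 / (1 - 0.5^6)
  expect_lt(abs(mean(thinned$ad) - condMean), 0.35)
  # expected surviving-site fraction = 1 - 2^-6
  expect_lt(abs(nrow(thinned) / 200 - (1 - 0.5^6)), 0.05)
  expect_true(all(thinned$ad >= 1L))
  expect_true(all(thinned$dp >= thinned$ad))
})

test_that("platform-exclusive calls key on contig, position, ref and alt", {
  a <- rbind(oneCall("c1", 10, "T", "G"), oneCall("c1", 20, "C", "A"))
  expect_equal(nrow(platformExclusiveCalls(a, a)), 0L)
  b <- oneCall("c2", 99, "T", "C")
  expect_equal(platformExclusiveCalls(a, b), a)
  # same position, different alt is retained
  b2 <- oneCall("c1", 10, "T", "C")
  expect_equal(nrow(platformExclusiveCalls(a, b2)), 2L)
})
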