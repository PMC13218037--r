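test_that("trinucleotide channels agree with an enumerated strand dictionary", {
  dict <- channelDictionary()
  cases <- expand.grid(l = BASES4, ref = BASES4, r = BASES4,
                       alt = BASES4, stringsAsFactors = FALSE)
  cases <- cases[cases$ref != cases$alt, ]
  genome <- smallGenome(c(c1 = "NA"))  # rebuilt per case below
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    genome <- smallGenome(c(c1 = paste0(cs$l, cs$ref, cs$r)))
    call <- oneCall("c1", 2, cs$ref, cs$alt)
    got <- trinucleotideChannel(genome, call)
    expect_equal(as.character(got),
                 dict[[paste(cs$l, cs$ref, cs$r, cs$alt)]],
                 info = paste(cs, collapse = " "))
  }
})

test_that("named examples and exclusions classify as documented", {
  g <- smallGenome(c(c1 = "GGATAGG"))
  expect_equal(as.character(trinucleotideChannel(g, oneCall("c1", 4, "T", "G"))),
               "A[T>G]A")
  g2 <- smallGenome(c(c1 = "GGTATGG"))
  expect_equal(as.character(trinucleotideChannel(g2, oneCall("c1", 4, "A", "C"))),
               "A[T>G]A")
  # contig edge and N context are excluded with a counter
  gEdge <- smallGenome(c(c1 = "TACG"))
  got <- trinucleotideChannel(gEdge, oneCall("c1", 1, "T", "G"))
  expect_true(is.na(got[1]))
  expect_equal(attr(got, "excluded"), 1L)
  gN <- smallGenome(c(c1 = "GNTAG"))
  expect_true(is.na(trinucleotideChannel(gN, oneCall("c1", 3, "T", "G"))[1]))
})

test_that("spectra count classifiable calls and are strand-symmetric", {
  set.seed(23)
  genome <- simulateReference(20000, 0.45)
  calls <- simulateTrueMutations(genome, 150)
  sp <- mutationSpectrum(genome, calls, mode = "96")
  expect_length(sp, 96L)
  chan <- trinucleotideChannel(genome, calls)
  expect_equal(sum(sp), sum(!is.na(chan)))

  # reverse-complement the genome and mirror the calls: same spectrum
  L <- nchar(as.character(genome[[1]]))
  rcGenome <- smallGenome(c(chrS = revcomp1(as.character(genome[[1]]))))
  rcCalls <- calls
  rcCalls$pos <- L - calls$pos + 1L
  rcCalls$ref <- comp1(calls$ref)
  rcCalls$alt <- comp1(calls$alt)
  expect_equal(mutationSpectrum(rcGenome, rcCalls, mode = "96"), sp)

  # single known call gives a one-hot 96-vector
  g1 <- smallGenome(c(c1 = "CCATACC"))
  sp1 <- mutationSpectrum(g1, oneCall("c1", 4, "T", "G"), mode = "96")
  expect_equal(sum(sp1), 1L)
  expect_equal(sp1[["A[T>G]A"]], 1L)
  # empty callset gives the zero vector
  expect_equal(sum(mutationSpectrum(g1, oneCall("c1", 4, "T", "G")[0, ])),
               0L)
  # 16-channel mode restricts to T>G
  sp16 <- mutationSpectrum(genome, calls, mode = "16TG")
  expect_length(sp16, 16L)
  cls <- collapseSBS(calls$ref, calls$alt)
  expect_equal(sum(sp16), sum(!is.na(chan) & cls == "T>G"))
})

test_that("base composition is calibrated on a uniform genome and sums to one", {
  set.seed(31)
  genome <- simulateReference(50000, 0.5)
  calls <- simulateTrueMutations(genome, 400)
  comp <- baseComposition(genome, calls, flank = 5L)
  expect_equal(nrow(comp), 10L * 4L)
  sums <- tapply(comp$fraction, comp$offset, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # i.i.d. uniform genome: each fraction's Wilson CI should cover ~0.25;
  # allow a small number of misses at 95% confidence
  covered <- comp$lower <= 0.25 & comp$upper >= 0.25
  expect_gt(mean(covered), 0.85)
  expect_true(all(abs(comp$background - 0.25) < 0.01))
})

test_that("G/C-selected artifact flanks show elevated C+G composition", {
  set.seed(37)
  cfg <- experimentConfig(genomeLength = 60000L, seed = 37L)
  genome <- simulateReference(cfg$genomeLength, cfg$gcFraction)
  art <- injectArtifacts(genome, oneCall("chrS", 500, "T", "G")[0, ], cfg)
  expect_gt(nrow(art), 50)
  comp <- baseComposition(genome, art, flank = 4L)
  cg <- tapply(comp$fraction[comp$base %in% c("C", "G")],
               comp$offset[comp$base %in% c("C", "G")], sum)
  bg <- sum(comp$background[comp$base %in% c("C", "G")][1:2])
  # offset +1 is constrained to T/G by artifact eligibility, not by the
  # G/C selection bias, so it is judged separately
  expect_true(all(cg[as.character(c(-4:-1, 2:4))] > bg))
  expect_gt(mean(cg > bg), 0.7)
})

test_that("k-mer motif ranking is consistent with composition and finds planted TCC", {
  set.seed(41)
  cfg <- experimentConfig(genomeLength = 60000L, seed = 41L)
  genome <- simulateReference(cfg$genomeLength, cfg$gcFraction)
  art <- injectArtifacts(genome, oneCall("chrS", 500, "T", "G")[0, ], cfg)
  top <- kmerMotifs(genome, art, k = 4L, side = "downstream")
  expect_equal(substr(names(top)[1], 1, 3), "TCC")
  expect_equal(sum(top), nrow(art))

  # k = 1 downstream reduces to the offset +1 column of the composition
  calls <- simulateTrueMutations(genome, 200)
  k1 <- kmerMotifs(genome, calls, k = 1L, side = "downstream")
  comp <- baseComposition(genome, calls, flank = 1L)
  plus1 <- comp[comp$offset == 1, ]
  expect_equal(unname(k1[plus1$base]),
               plus1$count)
})
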