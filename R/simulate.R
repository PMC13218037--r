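# Synthetic paired-platform experiment generator. Produces a reference, a
# shared set of true somatic mutations, a two-color-platform-only layer of
# planted T>G/A>C artifact sites with the characteristic context structure
# (NT[TG] eligibility, G/C-enriched flanks, a downstream TCC motif),
# and per-platform mismatch pileups — so every stage of the analysis runs
# and is testable without external sequencing data.

#' Configuration of a synthetic paired-platform experiment
#'
#' Defaults describe the emulated study conditions: a 300-kb uniform
#' random reference at 42% GC; two platforms at 30X mean depth; 300
#' shared true somatic mutations with allele fractions uniform on
#' \[0.05, 0.95\] and a uniform class spectrum; a per-read-base error rate
#' of 2e-3 (mismatches mostly at AD 1); and an artifact layer on the
#' two-color platform only, hitting 0.8% of eligible NT\[TG\] sites with
#' alternate depths from a truncated geometric (p = 0.35) on 2..10
#' (mode 2),
#' preferentially at sites with G/C-rich flanks within `gcFlank` bases
#' (selection weight exp(gcBias * #GC)) and a downstream TCC
#' trinucleotide (multiplicative weight tccWeight).
#'
#' @param genomeLength reference length in bases (>= 1000).
#' @param gcFraction genome G+C fraction, in (0, 1).
#' @param depth named vector of mean coverage per platform.
#' @param nTrueMutations number of shared true mutations.
#' @param afRange allele-fraction range of true mutations (uniform).
#' @param baseErrorRate per read-base miscall probability.
#' @param artifactRate probability an eligible NT\[TG\] site carries the
#'   artifact layer.
#' @param artifactADProbs named probability vector over artifact
#'   alternate depths (default truncated geometric, p = 0.35, support
#'   2..10).
#' @param gcBias log-weight per G/C base within +/-gcFlank of an
#'   eligible site.
#' @param tccWeight multiplicative weight for a downstream TCC context.
#' @param gcFlank half-width of the G/C bias window (default 4, the
#'   window the PWM filter observes).
#' @param seed integer seed; mandatory at simulation time.
#' @return A validated config list of class `duochromeConfig`.
#' @export
experimentConfig <- function(genomeLength = 300000L,
                             gcFraction = 0.42,
                             depth = c(nova = 30, hiseq = 30),
                             nTrueMutations = 300L,
                             afRange = c(0.05, 0.95),
                             baseErrorRate = 0.002,
                             artifactRate = 0.008,
                             artifactADProbs = NULL,
                             gcBias = 3.0,
                             tccWeight = 200,
                             gcFlank = 4L,
                             seed = NULL) {
  if (is.null(artifactADProbs)) {
    support <- 2:10
    w <- 0.35 * 0.65^(support - 2L)
    artifactADProbs <- w / sum(w)
    names(artifactADProbs) <- support
  }
  cfg <- list(genomeLength = as.integer(genomeLength),
              gcFraction = gcFraction,
              depth = depth,
              nTrueMutations = as.integer(nTrueMutations),
              afRange = afRange,
              baseErrorRate = baseErrorRate,
              artifactRate = artifactRate,
              artifactADProbs = artifactADProbs,
              gcBias = gcBias,
              tccWeight = tccWeight,
              gcFlank = as.integer(gcFlank),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  .validateConfig(cfg)
  class(cfg) <- c("duochromeConfig", "list")
  cfg
}

#' @noRd
.validateConfig <- function(cfg) {
  stopifnot(cfg$genomeLength >= 1000L,
            cfg$gcFraction > 0, cfg$gcFraction < 1,
            all(cfg$depth >= 1),
            all(c("nova", "hiseq") %in% names(cfg$depth)),
            cfg$nTrueMutations >= 0L,
            length(cfg$afRange) == 2L,
            cfg$afRange[1] > 0, cfg$afRange[2] <= 1,
            cfg$baseErrorRate >= 0, cfg$baseErrorRate <= 1,
            cfg$artifactRate >= 0, cfg$artifactRate <= 1,
            abs(sum(cfg$artifactADProbs) - 1) < 1e-9,
            all(as.integer(names(cfg$artifactADProbs)) >= 2L))
  invisible(TRUE)
}

#' Read/write an experiment configuration as YAML
#'
#' The configuration round-trips exactly (up to numeric formatting).
#'
#' @param cfg a config from [experimentConfig()].
#' @param path YAML path.
#' @export
writeConfig <- function(cfg, path) {
  plain <- lapply(unclass(cfg), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  toNamed <- function(x) unlist(x)
  experimentConfig(
    genomeLength = raw$genomeLength, gcFraction = raw$gcFraction,
    depth = toNamed(raw$depth), nTrueMutations = raw$nTrueMutations,
    afRange = unlist(raw$afRange), baseErrorRate = raw$baseErrorRate,
    artifactRate = raw$artifactRate,
    artifactADProbs = toNamed(raw$artifactADProbs),
    gcBias = raw$gcBias, tccWeight = raw$tccWeight,
    gcFlank = raw$gcFlank, seed = raw$seed)
}

#' Simulate an i.i.d. random reference genome
#'
#' @param length sequence length (>= 1000).
#' @param gcFraction target G+C fraction in (0, 1); G and C (and A and T)
#'   are equiprobable within their pair.
#' @param seed optional integer seed (NULL continues the current RNG
#'   stream).
#' @param contig contig name.
#' @return A single-contig [Biostrings::DNAStringSet].
#' @export
simulateReference <- function(length, gcFraction, seed = NULL,
                              contig = "chrS") {
  if (gcFraction <= 0 || gcFraction >= 1) {
    stop("gcFraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length < 1000L) stop("length must be >= 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  seq <- paste(sample(BASES, length, replace = TRUE, prob = p[BASES]),
               collapse = "")
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- contig
  out
}

#' Simulate shared true somatic mutations
#'
#' Draws distinct positions (reference base A/C/G/T), assigns each a
#' substitution class per `spectrumWeights` (uniform by default; for a
#' given reference base the three reachable classes are renormalised),
#' and an allele fraction uniform on `afRange`.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param n number of mutations; must be < genome length / 10.
#' @param afRange uniform AF range.
#' @param spectrumWeights named weights over [SBS_CLASSES].
#' @param seed optional integer seed.
#' @return A call table with contig, pos, ref, alt, af and
#'   truth = "true".
#' @export
simulateTrueMutations <- function(genome, n, afRange = c(0.05, 0.95),
                                  spectrumWeights = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spectrumWeights)) {
    spectrumWeights <- stats::setNames(rep(1 / 6, 6), SBS_CLASSES)
  }
  contig <- names(genome)[1L]
  cs <- .contigString(genome, contig)
  L <- nchar(cs)
  if (n >= L / 10) stop("n must be < genome length / 10", call. = FALSE)
  if (n == 0L) {
    out <- .emptyCalls()
    out$truth <- character(0)
    return(out)
  }
  refAll <- strsplit(cs, "")[[1L]]
  candidate <- which(refAll %in% BASES)
  pos <- sort(sample(candidate, n))
  ref <- refAll[pos]
  # per ref base the three reachable (ref>alt) pairs and their classes
  altChoices <- lapply(ref, function(r) setdiff(BASES, r))
  alt <- vapply(seq_len(n), function(i) {
    alts <- altChoices[[i]]
    w <- spectrumWeights[collapseSBS(rep(ref[i], 3L), alts)]
    sample(alts, 1L, prob = w / sum(w))
  }, character(1))
  af <- stats::runif(n, afRange[1], afRange[2])
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             af = af, truth = "true", stringsAsFactors = FALSE)
}

# Eligible artifact sites: reference T with 3' T/G, or the mirrored
# strand (reference A with 5' A/C, whose pyrimidine-frame 3' neighbour is
# then T/G). Returns positions, strand and selection weights. The G/C
# selection bias is counted over the +/-`flank` window around the site.
#' @noRd
.artifactEligibility <- function(genome, gcBias, tccWeight, flank = 4L) {
  contig <- names(genome)[1L]
  cs <- .contigString(genome, contig)
  L <- nchar(cs)
  refAll <- strsplit(cs, "")[[1L]]
  inRange <- (flank + 1L):(L - flank)
  nxt <- c(refAll[-1L], "N")
  prv <- c("N", refAll[-L])
  eligT <- inRange[refAll[inRange] == "T" &
                     nxt[inRange] %in% c("T", "G")]
  eligA <- inRange[refAll[inRange] == "A" &
                     prv[inRange] %in% c("A", "C")]
  pos <- c(eligT, eligA)
  strand <- rep(c("T", "A"), c(length(eligT), length(eligA)))
  if (!length(pos)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      weight = numeric(0)))
  }
  isGC <- as.integer(refAll %in% c("C", "G"))
  csGC <- cumsum(c(0L, isGC))
  nGC <- (csGC[pos + flank + 1L] - csGC[pos]) +
    (csGC[pos] - csGC[pos - flank])  # +/- flank, variant base excluded
  down <- ifelse(strand == "T",
                 substring(cs, pos + 1L, pos + 3L),
                 .revcomp(substring(cs, pos - 3L, pos - 1L)))
  w <- exp(gcBias * nGC) * ifelse(down == "TCC", tccWeight, 1)
  data.frame(pos = pos, strand = strand, weight = w,
             stringsAsFactors = FALSE)
}

#' Plant artifact T>G/A>C calls into the two-color platform's layer
#'
#' Artifact calls are placed only at eligible sites — reference T whose
#' 3' neighbour is T or G, or the strand mirror (reference A whose 5'
#' neighbour is A or C), i.e. N\[T>G\]\[TG\] contexts in the pyrimidine
#' frame — preferentially at sites whose +/-5 flank is G/C-rich and whose
#' downstream trinucleotide is TCC, per the config weights. Alternate
#' depths are drawn from `artifactADProbs`. Positions already carrying a
#' call are avoided.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param platformCalls the two-color platform's call table to augment.
#' @param config an [experimentConfig()].
#' @param seed optional integer seed.
#' @return `platformCalls` plus artifact rows (truth = "artifact", with
#'   `adFixed` the planted alternate depth).
#' @export
injectArtifacts <- function(genome, platformCalls, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  elig <- .artifactEligibility(genome, config$gcBias, config$tccWeight,
                               flank = config$gcFlank)
  elig <- elig[!(elig$pos %in% platformCalls$pos), , drop = FALSE]
  if (config$artifactRate == 0 || nrow(elig) == 0L) {
    if (config$artifactRate > 0) {
      stop("no eligible artifact sites (eligibility count 0)",
           call. = FALSE)
    }
    return(platformCalls)
  }
  nArt <- stats::rbinom(1L, nrow(elig), config$artifactRate)
  if (nArt == 0L) return(platformCalls)
  if (nArt > nrow(elig)) {
    stop("too few eligible artifact sites (", nrow(elig), " available)",
         call. = FALSE)
  }
  pick <- sample(nrow(elig), nArt, prob = elig$weight)
  sel <- elig[pick, , drop = FALSE]
  ad <- sample(as.integer(names(config$artifactADProbs)), nArt,
               replace = TRUE, prob = config$artifactADProbs)
  art <- data.frame(
    contig = names(genome)[1L],
    pos = sel$pos,
    ref = sel$strand,
    alt = ifelse(sel$strand == "T", "G", "C"),
    af = NA_real_,
    truth = "artifact",
    stringsAsFactors = FALSE)
  art$adFixed <- ad
  if (!"adFixed" %in% names(platformCalls)) {
    platformCalls$adFixed <- rep(NA_integer_, nrow(platformCalls))
  }
  common <- union(names(platformCalls), names(art))
  for (nm in setdiff(common, names(art))) art[[nm]] <- NA
  for (nm in setdiff(common, names(platformCalls))) {
    platformCalls[[nm]] <- rep(NA, nrow(platformCalls))
  }
  out <- rbind(platformCalls[common], art[common])
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate per-site mismatch pileups for one platform
#'
#' Every call site receives `adFixed` supporting reads (artifact layer)
#' or a Binomial(dp, af) draw (true mutations) out of a
#' Binomial(2*depth, 1/2)-distributed total depth; every other position
#' can gain error mismatches at `errorRate` per read base, uniform over
#' the three alternate alleles (so mostly AD 1). Sites with no alternate
#' reads are not emitted.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param calls call table (true and/or artifact rows).
#' @param depth mean coverage.
#' @param errorRate per read-base miscall probability.
#' @param seed optional integer seed.
#' @param platform label for the output.
#' @return A list: `mismatches` (PileupMismatch data.frame with truth
#'   labels, "error" for noise sites) and `coverage` (per-contig integer
#'   depth vectors).
#' @export
simulatePileups <- function(genome, calls, depth, errorRate, seed = NULL,
                            platform = "sample") {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  contig <- names(genome)[1L]
  cs <- .contigString(genome, contig)
  L <- nchar(cs)
  refAll <- strsplit(cs, "")[[1L]]
  cov <- stats::rbinom(L, 2L * round(depth), 0.5)

  # call layer
  nC <- nrow(calls)
  callRows <- NULL
  if (nC) {
    dpC <- pmax(cov[calls$pos], 1L)
    adFixed <- if ("adFixed" %in% names(calls)) calls$adFixed else
      rep(NA_integer_, nC)
    ad <- integer(nC)
    free <- is.na(adFixed)
    ad[free] <- stats::rbinom(sum(free), dpC[free], calls$af[free])
    ad[!free] <- pmin(adFixed[!free], dpC[!free])
    keep <- ad >= 1L
    callRows <- data.frame(
      contig = contig, pos = calls$pos[keep], ref = calls$ref[keep],
      alt = calls$alt[keep], ad = as.integer(ad[keep]),
      dp = as.integer(dpC[keep]),
      truth = if ("truth" %in% names(calls)) calls$truth[keep] else "true",
      stringsAsFactors = FALSE)
  }

  # error layer at non-call positions
  isCall <- logical(L)
  if (nC) isCall[calls$pos] <- TRUE
  errN <- stats::rbinom(L, cov, errorRate)
  errPos <- which(errN > 0L & !isCall & refAll %in% BASES)
  errRows <- NULL
  if (length(errPos)) {
    k <- errN[errPos]
    single <- k == 1L
    altPick <- character(length(errPos))
    # single-error sites: one uniform alternate
    altIdx <- (match(refAll[errPos[single]], BASES) - 1L +
                 sample.int(3L, sum(single), replace = TRUE)) %% 4L + 1L
    altPick[single] <- BASES[altIdx]
    rows <- list(data.frame(
      contig = contig, pos = errPos[single], ref = refAll[errPos[single]],
      alt = altPick[single], ad = 1L, dp = cov[errPos[single]],
      truth = "error", stringsAsFactors = FALSE))
    # multi-error sites: split across the three alternates
    for (i in which(!single)) {
      p <- errPos[i]
      alts <- setdiff(BASES, refAll[p])
      split <- as.integer(stats::rmultinom(1L, k[i], rep(1 / 3, 3L)))
      hit <- split > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, pos = p, ref = refAll[p], alt = alts[hit],
        ad = split[hit], dp = cov[p], truth = "error",
        stringsAsFactors = FALSE)
    }
    errRows <- do.call(rbind, rows)
  }
  mm <- rbind(callRows, errRows)
  if (is.null(mm)) {
    mm <- data.frame(contig = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     ad = integer(0), dp = integer(0),
                     truth = character(0), stringsAsFactors = FALSE)
  }
  mm <- mm[order(mm$pos, mm$alt), , drop = FALSE]
  mm$platform <- rep(platform, nrow(mm))
  rownames(mm) <- NULL
  list(mismatches = mm, coverage = stats::setNames(list(cov), contig))
}

#' Simulate a complete paired-platform experiment
#'
#' Both platforms share one reference and one set of true mutations;
#' only the two-color ("nova") platform receives the planted artifact
#' layer. Per-platform mismatch pileups are realised independently, and
#' per-platform callsets are derived from the realised pileups at call
#' sites with alternate depth >= `minCallAD` (mirroring the alt-AD >= 2
#' retention rule of the variant-level analysis). Fully deterministic
#' under the config seed.
#'
#' @param config an [experimentConfig()] with a non-NULL seed.
#' @param outDir optional directory; when given, FASTA, per-platform
#'   pileup/truth TSVs, callset VCFs and the config YAML are written.
#' @param minCallAD minimum realised alternate depth for a call to enter
#'   the platform callset.
#' @return A list with `genome`, `config`, and per-platform elements
#'   `nova` and `hiseq`, each holding `pileups`, `coverage`, `calls`
#'   (realised callset with truth labels) and `truth` (planted truth
#'   table).
#' @export
simulatePairedExperiment <- function(config, outDir = NULL,
                                     minCallAD = 2L) {
  .validateConfig(config)
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  set.seed(config$seed)
  genome <- simulateReference(config$genomeLength, config$gcFraction)
  true <- simulateTrueMutations(genome, config$nTrueMutations,
                                afRange = config$afRange)
  novaTruth <- injectArtifacts(genome, true, config)
  hiseqTruth <- true

  platformData <- function(truthCalls, platform) {
    sim <- simulatePileups(genome, truthCalls, config$depth[[platform]],
                           config$baseErrorRate, platform = platform)
    mm <- sim$mismatches
    isCall <- mm$truth %in% c("true", "artifact")
    calls <- mm[isCall & mm$ad >= minCallAD, , drop = FALSE]
    calls$af <- calls$ad / calls$dp
    rownames(calls) <- NULL
    list(pileups = mm, coverage = sim$coverage, calls = calls,
         truth = truthCalls)
  }
  nova <- platformData(novaTruth, "nova")
  hiseq <- platformData(hiseqTruth, "hiseq")
  out <- list(genome = genome, config = config, nova = nova,
              hiseq = hiseq)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(genome, file.path(outDir, "reference.fa"))
    writeConfig(config, file.path(outDir, "config.yaml"))
    for (pl in c("nova", "hiseq")) {
      writeMismatchTable(out[[pl]]$pileups,
                         file.path(outDir, paste0(pl, "_pileups.tsv")))
      utils::write.table(out[[pl]]$truth,
                         file.path(outDir, paste0(pl, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeVariants(out[[pl]]$calls,
                    file.path(outDir, paste0(pl, "_calls.vcf")),
                    sampleName = pl)
    }
  }
  out
}

#' Write synthetic aligned reads as SAM (and a read-record table)
#'
#' Generates clean paired-flag reads (MAPQ 60, proper pairs, all-M
#' CIGARs, uniform high base qualities) tiling a region, with planted
#' mismatches at call sites on `ad` of the covering reads. Used to
#' produce desk-scale read-level fixtures that pass [readQC()] by
#' construction.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param calls call table; each site's `ad` (or `adFixed`) covering
#'   reads carry the alternate base.
#' @param depth reads covering each position (approximate).
#' @param readLength read length (101 by default).
#' @param qual constant per-base Phred quality.
#' @param seed optional integer seed.
#' @param path optional SAM output path.
#' @return The read-record data.frame (same shape as
#'   [readAlignments()]).
#' @export
simulateReads <- function(genome, calls, depth = 10L, readLength = 101L,
                          qual = 37L, seed = NULL, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contig <- names(genome)[1L]
  cs <- .contigString(genome, contig)
  L <- nchar(cs)
  if (L < readLength) stop("contig shorter than the read length",
                           call. = FALSE)
  nReads <- max(1L, round(depth * L / readLength))
  starts <- sort(sample.int(L - readLength + 1L, nReads, replace = TRUE))
  bases <- substring(cs, starts, starts + readLength - 1L)
  # plant mismatches: per call, the first `ad` covering reads get the alt
  adWanted <- if ("adFixed" %in% names(calls)) {
    ifelse(is.na(calls$adFixed), calls$ad, calls$adFixed)
  } else calls$ad
  basesSplit <- strsplit(bases, "")
  for (i in seq_len(nrow(calls))) {
    p <- calls$pos[i]
    covering <- which(starts <= p & starts + readLength - 1L >= p)
    take <- utils::head(covering, adWanted[i])
    for (r in take) basesSplit[[r]][p - starts[r] + 1L] <- calls$alt[i]
  }
  bases <- vapply(basesSplit, paste, character(1), collapse = "")
  reads <- data.frame(
    name = sprintf("read%06d", seq_len(nReads)),
    contig = contig, pos = starts, mapq = 60L, mapped = TRUE,
    properPair = TRUE, supplementary = FALSE, duplicate = FALSE,
    cigar = paste0(readLength, "M"), bases = bases,
    lengthClass = if (readLength <= 126L) 101L else
      if (readLength <= 200L) 151L else 250L,
    stringsAsFactors = FALSE)
  reads$quals <- rep(list(rep(as.integer(qual), readLength)), nReads)
  if (!is.null(path)) writeSam(reads, genome, path)
  reads
}

#' Write a read-record table as SAM
#'
#' Minimal SAM emitter for synthetic fixtures (no installed R package
#' writes SAM records from scratch). Flags are reconstructed from the
#' logical columns; qualities are Phred+33 encoded.
#'
#' @param reads read-record data.frame.
#' @param genome reference [Biostrings::DNAStringSet] (for @SQ lines).
#' @param path output SAM path.
#' @export
writeSam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  flag <- 1L +                      # paired
    ifelse(reads$properPair, 2L, 0L) +
    ifelse(reads$mapped, 0L, 4L) +
    ifelse(reads$duplicate, 1024L, 0L) +
    ifelse(reads$supplementary, 2048L, 0L) +
    64L                             # first of pair
  qualStr <- vapply(reads$quals, function(q) {
    intToUtf8(q + 33L)
  }, character(1))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   reads$name, flag, reads$contig, reads$pos, reads$mapq,
                   reads$cigar, reads$bases, qualStr)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
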