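#' Run the full synthetic paired-platform analysis
#'
#' Orchestrates the pipeline end to end on a synthetic experiment:
#' simulation, per-platform AD spectra, per-AD T>G enrichment testing
#' with FDR control, trinucleotide spectra, flanking base composition,
#' k-mer motif ranking, and PWM likelihood-ratio correction of the
#' two-color platform's callset. All stage tables are returned; when
#' `outDir` is given they are also written as TSV together with a JSON
#' manifest (package version, seed, config digest).
#'
#' @param config an [experimentConfig()] with a seed (a path to a YAML
#'   config is also accepted).
#' @param outDir optional output directory.
#' @param alpha significance/FDR level used throughout.
#' @param adMax top allele-depth bin of the spectra.
#' @param classes substitution classes passed to [correctCallset()].
#' @return A list with elements `experiment`, `adNova`, `adHiseq`,
#'   `enrichment`, `spectrumNova`, `spectrumHiseq`, `composition`,
#'   `motifs`, `correction`, `manifest`.
#' @export
runAll <- function(config, outDir = NULL, alpha = 0.05, adMax = 25L,
                   classes = SBS_CLASSES) {
  if (is.character(config)) config <- readConfig(config)
  if (is.null(config$seed)) {
    stop("config field 'seed' is required", call. = FALSE)
  }
  exp <- simulatePairedExperiment(config, outDir = outDir)

  adNova <- adSpectrum(exp$nova$pileups, adMax = adMax)
  adHiseq <- adSpectrum(exp$hiseq$pileups, adMax = adMax)
  enrich <- perADEnrichment(adNova, adHiseq, class = "T>G",
                            alpha = alpha)

  spNova <- mutationSpectrum(exp$genome, exp$nova$calls, mode = "96")
  spHiseq <- mutationSpectrum(exp$genome, exp$hiseq$calls, mode = "96")
  tgNova <- exp$nova$calls[collapseSBS(exp$nova$calls$ref,
                                       exp$nova$calls$alt) == "T>G", ,
                           drop = FALSE]
  comp <- baseComposition(exp$genome, tgNova, flank = 5L)
  motifs <- kmerMotifs(exp$genome, tgNova, k = 4L, side = "downstream")

  corr <- correctCallset(exp$nova$calls, exp$genome,
                         trainingNova = exp$nova$calls,
                         trainingHiseq = exp$hiseq$calls,
                         alpha = alpha, classes = classes)

  manifest <- list(
    package = as.character(utils::packageVersion("duochromeQC")),
    seed = config$seed,
    configDigest = .configDigest(config),
    nTrueMutations = config$nTrueMutations,
    genomeLength = config$genomeLength)

  out <- list(experiment = exp, adNova = adNova, adHiseq = adHiseq,
              enrichment = enrich, spectrumNova = spNova,
              spectrumHiseq = spHiseq, composition = comp,
              motifs = motifs, correction = corr, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(enrich, file.path(outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(channel = names(spNova), nova = spNova,
                 hiseq = spHiseq, row.names = NULL),
      file.path(outDir, "spectra96.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comp, file.path(outDir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(kmer = names(motifs), count = as.integer(motifs)),
      file.path(outDir, "motifs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(corr$summary, file.path(outDir, "correction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeVariants(corr$kept, file.path(outDir, "nova_corrected.vcf"),
                  sampleName = "nova")
    if (nrow(corr$flagged)) {
      writeVariants(corr$flagged, file.path(outDir, "nova_flagged.vcf"),
                    annotations = rep(TRUE, nrow(corr$flagged)),
                    sampleName = "nova")
    }
    if (length(corr$pwms)) {
      writePWMs(corr$pwms, file.path(outDir, "pwms.json"))
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

# Stable digest of a config: serialised YAML text fed through a small
# FNV-1a hash (enough to detect config drift between runs).
#' @noRd
.configDigest <- function(config) {
  txt <- yaml::as.yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
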