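# Readers/writers for the standard formats the pipeline touches, normalised
# into the package's tabular domain types. Coordinates are 1-based inclusive
# everywhere (the R/Bioconductor convention), matching VCF positions on disk.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and multi-line records concatenated. Contig
#' names are the first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique contig names.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", "ACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L ||
      !any(startsWith(readLines(path, n = 50L, warn = FALSE), ">"))) {
    warning("FASTA file '", path, "' contains no records", call. = FALSE)
    return(Biostrings::DNAStringSet())
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1L]
    stop("duplicate contig name in FASTA: '", dup, "'", call. = FALSE)
  }
  # normalise case (soft-masked references use lowercase)
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Read biallelic SNVs from a VCF into a variant-call table
#'
#' Extracts biallelic single-nucleotide records; multi-allelic records,
#' indels and records lacking both AD and DP FORMAT fields are skipped and
#' counted. `ad` is the first sample's alternate allele depth (second AD
#' entry), `dp` the first sample's DP (or the AD sum when DP is missing),
#' and `af` is always recomputed as `ad/dp` — never trusted from the file.
#'
#' @param path path to a VCF 4.x file.
#' @param platform label recorded in the `platform` column.
#' @return A data.frame with columns contig, pos (1-based), ref, alt, ad,
#'   dp, af, platform, and any INFO flags named in the header as logical
#'   columns. Skipped-record counts are attached as `attr(x, "skipped")`.
#' @export
readVariants <- function(path, platform = "sample") {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = "unspecified")
  n <- length(vcf)
  skipped <- c(multiallelic = 0L, not_snv = 0L, no_depth = 0L)
  if (n == 0L) {
    out <- .emptyCalls()
    attr(out, "skipped") <- skipped
    return(out)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altList)
  multi <- nAlt != 1L
  altChr <- rep(NA_character_, n)
  altChr[!multi] <- as.character(unlist(altList[!multi]))
  snv <- !multi & nchar(ref) == 1L & !is.na(altChr) & nchar(altChr) == 1L &
    ref %in% BASES & altChr %in% BASES
  skipped["multiallelic"] <- sum(multi)
  skipped["not_snv"] <- sum(!multi & !snv)

  g <- VariantAnnotation::geno(vcf)
  ad <- rep(NA_integer_, n)
  dp <- rep(NA_integer_, n)
  adSum <- rep(NA_integer_, n)
  if ("AD" %in% names(g)) {
    adField <- g$AD
    adFirst <- if (length(dim(adField)) == 3L) {
      lapply(seq_len(n), function(i) adField[i, 1L, ])
    } else {
      adField[, 1L]
    }
    ad <- vapply(adFirst, function(v) {
      if (length(v) >= 2L && !all(is.na(v))) as.integer(v[2L]) else NA_integer_
    }, integer(1))
    adSum <- vapply(adFirst, function(v) {
      if (all(is.na(v))) NA_integer_ else as.integer(sum(v, na.rm = TRUE))
    }, integer(1))
  }
  if ("DP" %in% names(g)) dp <- as.integer(g$DP[, 1L])
  dp <- ifelse(is.na(dp), adSum, dp)
  hasDepth <- !is.na(ad) & !is.na(dp)
  skipped["no_depth"] <- sum(snv & !hasDepth)

  keep <- snv & hasDepth
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep],
    alt = altChr[keep],
    ad = ad[keep],
    dp = dp[keep],
    stringsAsFactors = FALSE
  )
  out$af <- ifelse(out$dp > 0L, out$ad / out$dp, NA_real_)
  out$platform <- platform
  infoDF <- VariantAnnotation::info(vcf)
  for (fl in names(infoDF)) {
    if (is.logical(infoDF[[fl]])) out[[fl]] <- infoDF[[fl]][keep]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a variant-call table as VCF
#'
#' Emits a valid single-sample VCF 4.2 with AD/DP FORMAT fields that
#' round-trips through [readVariants()]. When `annotations` is supplied,
#' flagged calls carry the `TG_ARTIFACT` INFO flag.
#'
#' @param calls variant-call data.frame (contig, pos, ref, alt, ad, dp).
#' @param path output path.
#' @param annotations optional logical vector, one per call: artifact flag.
#' @param sampleName sample column name in the VCF.
#' @return The path, invisibly.
#' @export
writeVariants <- function(calls, path, annotations = NULL,
                          sampleName = "SAMPLE") {
  .checkCalls(calls)
  n <- nrow(calls)
  if (is.null(annotations)) {
    annotations <- if ("TG_ARTIFACT" %in% names(calls)) {
      calls$TG_ARTIFACT
    } else {
      rep(FALSE, n)
    }
  }
  stopifnot(length(annotations) == n)
  ord <- order(calls$contig, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  annotations <- annotations[ord]

  if (n == 0L) {
    # header-only VCF (writeVcf emits a malformed contig line for an
    # empty GRanges, so the trivial case is written directly)
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0("##INFO=<ID=TG_ARTIFACT,Number=0,Type=Flag,Description=",
             "\"Flagged as a two-color-chemistry sequencing artifact\">"),
      paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
             "\"Allelic depths for the ref and alt alleles\">"),
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sampleName), collapse = "\t")), path)
    return(invisible(path))
  }

  hdr <- VariantAnnotation::VCFHeader(samples = sampleName)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = "0", Type = "Flag",
    Description = "Flagged as a two-color-chemistry sequencing artifact",
    row.names = "TG_ARTIFACT")
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = c("R", "1"), Type = c("Integer", "Integer"),
    Description = c("Allelic depths for the ref and alt alleles",
                    "Total read depth"),
    row.names = c("AD", "DP"))

  gr <- GenomicRanges::GRanges(calls$contig,
                               IRanges::IRanges(calls$pos, width = 1L))
  fixedDF <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(calls$ref),
    ALT = Biostrings::DNAStringSetList(as.list(calls$alt)),
    QUAL = rep(NA_real_, n), FILTER = rep("PASS", n))
  adMat <- matrix(mapply(function(a, d) c(d - a, a), calls$ad, calls$dp,
                         SIMPLIFY = FALSE),
                  ncol = 1L, dimnames = list(NULL, sampleName))
  dpMat <- matrix(as.integer(calls$dp), ncol = 1L,
                  dimnames = list(NULL, sampleName))
  if (n == 0L) adMat <- matrix(list(), 0L, 1L,
                               dimnames = list(NULL, sampleName))
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = sampleName),
    exptData = list(header = hdr),
    fixed = fixedDF,
    info = S4Vectors::DataFrame(TG_ARTIFACT = as.logical(annotations)),
    geno = S4Vectors::SimpleList(AD = adMat, DP = dpMat),
    collapsed = TRUE)
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read aligned reads from SAM or BAM into a read-record table
#'
#' SAM input is converted in place (to a temporary BAM) via
#' [Rsamtools::asBam()]. Each record yields one row; unmapped reads are
#' kept with `mapped = FALSE` so downstream filters can count them.
#'
#' @param path path to a SAM or BAM file with a header.
#' @return A data.frame with columns name, contig, pos (1-based leftmost),
#'   mapq, mapped, properPair, supplementary, duplicate, cigar, bases,
#'   lengthClass (nearest of 101/151/250), and a list-column `quals` of
#'   per-base Phred integers.
#' @export
readAlignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "seq", "qual")))[[1L]]
  n <- length(res$qname)
  bases <- as.character(res$seq)
  qual <- as(res$qual, "IntegerList")
  quals <- as.list(qual)
  badQ <- vapply(seq_len(n), function(i) {
    length(quals[[i]]) != nchar(bases[i])
  }, logical(1))
  if (any(badQ)) {
    stop("read '", res$qname[which(badQ)[1L]],
         "' has no per-base quality string", call. = FALSE)
  }
  flag <- res$flag
  out <- data.frame(
    name = res$qname,
    contig = as.character(res$rname),
    pos = res$pos,
    mapq = as.integer(res$mapq),
    mapped = bitwAnd(flag, 4L) == 0L,
    properPair = bitwAnd(flag, 2L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    cigar = res$cigar,
    bases = bases,
    stringsAsFactors = FALSE
  )
  len <- nchar(bases)
  classes <- c(101L, 151L, 250L)
  out$lengthClass <- if (n) {
    classes[max.col(-abs(outer(len, classes, "-")))]
  } else {
    integer(0)
  }
  out$quals <- quals
  out
}

#' Read or write the simplified per-site mismatch/call TSV dialect
#'
#' A plain table with columns contig, pos, ref, alt, ad, dp, platform is
#' accepted everywhere a VCF is, for desk-scale fixtures. Extra columns
#' (af, truth labels, flags) round-trip unchanged.
#'
#' @param path TSV path.
#' @return `readMismatchTable`: the validated data.frame (with `af`
#'   recomputed from ad/dp).
#' @export
readMismatchTable <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  .checkCalls(x)
  x$pos <- as.integer(x$pos)
  x$ad <- as.integer(x$ad)
  x$dp <- as.integer(x$dp)
  x$af <- ifelse(x$dp > 0L, x$ad / x$dp, NA_real_)
  x
}

#' @rdname readMismatchTable
#' @param x a mismatch/call table.
#' @export
writeMismatchTable <- function(x, path) {
  toWrite <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(toWrite, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
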