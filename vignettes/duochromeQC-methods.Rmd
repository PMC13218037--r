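---
title: "Detecting and correcting the two-color chemistry T>G artifact"
author: "duochromeQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting the two-color chemistry T>G artifact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Illumina's two-color base-calling chemistry (NovaSeq-type instruments)
encodes the four nucleotides with two dyes: T green, C red, A both, G
neither. A G call is therefore indistinguishable from a loss of signal —
cluster degradation, a blocked flow-cell region, a failed cycle. The
practical consequence is a platform-specific excess of T>G (and, on the
opposite strand, A>C) substitutions. The excess is small in absolute
terms: it does not disturb germline calling or somatic calling with a
matched normal. It matters precisely where variant evidence is weakest —
mosaic-mutation studies in non-cancerous tissue, where variants sit at
1–10% allele fraction, are supported by a handful of reads, and are
called without a matched control. There, an artifact that concentrates
at alternate allele depths (AD) of 2–10 is indistinguishable in depth
profile from the rarest real mutations.

duochromeQC implements the full detection-and-correction analysis for
paired datasets from a two-color and a four-color platform: stringent
read-level QC, AD-stratified mismatch profiling, per-AD two-proportion
testing with FDR control, trinucleotide and flanking-base context
analysis, and a position-weight-matrix (PWM) likelihood-ratio filter
that removes artifact-prone calls from a callset. A synthetic
paired-platform generator reproduces the statistical structure of such
experiments so every stage is testable without external data.

## Read-level QC

The read filters are deliberately harsher than pre-variant-calling QC:
the goal is a clean substrate for mismatch counting, not yield.

* Fixed trims: the final 5 bp of every read (read-end quality
  degradation) and the first 8 bp of 101-bp reads or 12 bp of
  151/250-bp reads (read-start adapter contamination).
* Quality scan: mean Phred quality in 10-bp sliding windows (step 1,
  windows wholly inside the read); at the first window whose mean drops
  below 25, the read is cut at the window's leftmost position. The mean
  is taken on the Phred scale, not on error probabilities.
* Length filter: at least 65 retained bases for the 101-bp class, 100
  for 151/250 (inclusive comparison).
* Alignment filters: drop duplicates, non-proper pairs, supplementary
  alignments, MAPQ < 60, and any CIGAR containing I/D/S/H. Reasons are
  reported in a fixed order (unmapped, duplicate, proper-pair,
  supplementary, MAPQ, CIGAR); the kept set is order-invariant, and
  `readQC()` runs the alignment filters first so that surviving reads
  are all-M and the trims shift alignment starts trivially.

Two readings were genuinely open: whether the head trim precedes the
tail trim (the operations commute — irrelevant), and whether the
quality scan runs on the raw or fixed-trimmed read. We scan the
fixed-trimmed read, matching the order in which the rules are stated.

## Mismatch profiling

A mismatch *site* is a (position, alternate allele) pair — one position
can contribute up to three sites. Substitutions are collapsed into the
six pyrimidine-referenced SBS classes (A>C becomes T>G, and so on),
since strand of origin is unobservable. Sites are stratified by AD into
an `ADMatrix` (6 classes × AD 1..25 by default); depths above the top
bin accumulate there rather than being dropped, so totals are
conserved. A *platform-specific* site is mismatched on one platform and
absent from the other — absence only counts where the other platform
has coverage (`minOtherDepth`, default 1), since "not detected" is
meaningless over a coverage gap. `downsampleSites()` implements
binomial thinning of both ad and dp for coverage-matched re-analysis,
and `recalculateAD()` re-derives call ADs from pileups, retaining calls
with recomputed AD ≥ 2.

## Enrichment testing

For each AD stratum, the T>G share of all mismatch sites is compared
between platforms with the pooled two-proportion z statistic

$$z = \frac{p_{\mathrm{Nova}} - p_{\mathrm{HiSeq}}}
{\sqrt{p(1-p)\left(\tfrac{1}{n_{\mathrm{Nova}}} +
\tfrac{1}{n_{\mathrm{HiSeq}}}\right)}},$$

with $p$ the pooled proportion, two-sided p-values from the standard
normal, and no continuity correction (fidelity to the statistic as
printed). Degenerate pooled proportions (0 or 1) return z = 0, p = 1.
q-values are Benjamini–Hochberg adjusted p-values (a Storey-type
estimate is available via `fdrMethod = "storey"`); BH was chosen as the
default because it is deterministic and parameter-free. The
multiple-testing family is the set of AD strata of one
sample-and-class comparison — the unit in which results are inspected —
not all samples jointly. The AD = 1 stratum is computed but flagged
`disregarded`: single-read mismatches predominantly reflect residual
random sequencing or alignment error and are never counted as
significant.

## Sequence context

`mutationSpectrum()` classifies calls into the 96 COSMIC trinucleotide
channels (or the 16 N[T>G]N channels), reverse-complementing
purine-referenced calls into the pyrimidine frame.
`baseComposition()` profiles the base fractions at every offset within
±5 of a call against the genome-wide background, with Wilson score 95%
intervals (stable at small n; the interval method was unspecified
upstream). `kmerMotifs()` ranks the k-mer immediately 3′ (or 5′) of
calls with a deterministic lexicographic tie-break. Both the context
and the window are flipped for purine-referenced calls so the artifact
motifs of the two strands co-accumulate; `orient = "as-read"`
preserves the per-strand view.

## The PWM likelihood-ratio filter

The artifact concentrates at N[T>G][TG] trinucleotides with G/C-rich
flanks and a characteristic downstream TCC motif, which makes local
sequence context a usable classifier even when trinucleotide context
alone is not. For each substitution class, one PWM per platform is
trained on the 8-base windows around calls (4 bases per side; the
variant base is excluded — within a class it is constant and carries no
information). Training uses a Laplace pseudocount of 1, guaranteeing
finite log-ratios. Each call is scored with

$$\ell(w) = \sum_{j} \log
\frac{P_{\mathrm{Nova}}[j, w_j]}{P_{\mathrm{HiSeq}}[j, w_j]},$$

and compared against the *exact* null distribution of $\ell$ when the
window is drawn position-independently from the four-color-platform
PWM, computed by convolving the eight per-position four-outcome
log-ratio distributions (≤ 4^8 atoms; atoms are merged at 1e-12). The
p-value is the inclusive upper tail $P(\ell_{\mathrm{null}} \ge
\ell_{\mathrm{obs}})$ — inclusive ties are the conservative choice —
and calls with p < 0.05 are flagged. The exact convolution null is this
package's realisation of "significantly more likely under the two-color
PWM": the position-independence the PWM already assumes determines it
uniquely, and it is computable exactly at desk scale.

The filter runs class-wise on all six classes by default (the correction
is known to rescale T>C as well as T>G; restricting `classes` gives a
conservative variant). Training and test callsets may coincide, as in
the source analysis; no cross-validation split is imposed.

## The synthetic generator

`simulatePairedExperiment()` emulates the paired design: one reference,
one set of true somatic mutations shared by both platforms, and an
artifact layer added to the two-color platform only. Defaults define
the emulated study conditions and were fixed once, during design:

* genome: 300 kb i.i.d. sequence at 42% GC — roughly genomic base
  composition; long enough that every AD stratum up to 25 is populated
  and the artifact-eligible site pool is not exhausted by selection.
* depth 30X per platform (the coverage class where the artifact begins
  to reach callable ADs); per-read-base error 2e-3, producing mismatch
  noise mostly at AD 1, as after stringent QC.
* 300 true mutations with AF uniform on [0.05, 0.95] (a broad mosaic-to
  clonal range) and a uniform class spectrum; per-platform ad/dp are
  independent binomial realisations at each platform's depth, and
  callsets retain calls with realised AD ≥ 2.
* artifact layer: 0.8% of eligible sites — reference T with 3′ T or G,
  or the strand mirror — gain a T>G (A>C) mismatch with AD from a
  truncated geometric (p = 0.35) on 2..10, mode 2, matching the
  observed concentration of the artifact at AD 2–5. Sites are selected
  with weight $e^{3 \cdot \#GC}$ over the ±4 flank and ×200 for a
  downstream TCC trinucleotide, producing G/C-enriched flanks and a
  [T>G]TCC-like top motif. The G/C window is ±4 rather than ±5 so that
  the planted context signal lies in the window the PWM filter
  observes; with a ±5 window part of the selection weight falls outside
  the 8-base window and the planted artifact becomes less separable
  than the real one (which the source correction removes 25-fold).
  The bias strengths were set so that artifact windows are PWM-separable
  from background at the ~95% level — the regime the real artifact's
  reported fold-reductions imply — and then frozen.

All randomness flows from the single config seed through one RNG
stream; identical seeds give byte-identical output files.

What the generator does *not* emulate: alignment ambiguity, PCR
duplicates, fragment-length structure, diploid genotypes, GC-dependent
coverage, or any dependence of the error layer on sequence context.
Consequently, passing tests demonstrate that the statistical machinery
recovers planted structure under the stated model — not that real
NovaSeq data will separate as cleanly; on real data the artifact's
context signal is entangled with mappability and library effects that
this model idealises away.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout, the R/Bioconductor
  convention, matching VCF positions on disk.
* `tgFraction()` returns NA (not 0) for an empty AD stratum; enrichment
  rows untestable on both platforms are marked rather than guessed.
* Null-distribution atoms are merged after rounding scores to 12
  decimals; survival lookups use a 1e-9 tolerance so ties at the
  observed score are included (conservative).
* Sites or calls whose context window touches N or a contig edge are
  excluded and counted, never silently dropped.
* VCF allele fractions are always recomputed as ad/dp; the file's AF is
  never trusted.

## Problem sizes

The test suite and the acceptance script run the generator at its
default 300-kb scale: single experiments take on the order of a second,
the 100-seed calibration and power studies a couple of minutes. The
brute-force oracles (full 4^8 enumeration of the PWM null, per-column
pileup counting, window-by-window trim scans) run on reduced instances
chosen to finish in seconds while still exercising every code path.

## Known limitations

* The per-AD test treats strata as independent; a site family spanning
  several ADs after downsampling is re-tested without dependency
  adjustment, as in the source analysis.
* The PWM null assumes positional independence of flanking bases; real
  genomic context is autocorrelated, so real-data p-values are
  approximate even though the null is exact under the model.
* SAM/BAM ingestion targets clean single-end-representable records
  (mate information is reduced to the proper-pair flag); CRAM and
  multi-sample VCF semantics beyond the first sample are out of scope.
* With training callsets in the low tens of windows per class, PWM
  noise inflates the effective false-flag rate above alpha; the
  calibration test quantifies this at ~5–8%.
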