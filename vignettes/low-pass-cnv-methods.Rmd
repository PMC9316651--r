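---
title: "Single-cell low-pass CNV profiling and QC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell low-pass CNV profiling and QC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclpCNV)
```

# Scope and model

`sclpCNV` turns mapped read positions from a single whole-genome-amplified
cell — typically a circulating tumor cell (CTC) sequenced at low pass — into
a windowed copy-number (CN) profile with integer, arm-level and gene-level
calls, after passing the cell through the standard single-cell QC battery.
The package deliberately starts *after* alignment: its inputs are mapped
positions (SAM/BAM or a plain positions table), a genome model, and optional
blacklist/gene BEDs. Alignment, sequence-level simulation and SNV calling
are out of scope.

## Coordinate system

All internal coordinates are 0-based half-open; BED input is used natively
and SAM's 1-based positions are converted at the reader boundary. The
default genome model is hg19-like: 22 autosomes plus X for a female sample
(23 chromosomes — the configuration used throughout, matching a female
patient), with Y available as a configuration switch. Chromosome arms are
half-open at the centromere: a position at the centromere coordinate belongs
to the q arm. The shipped centromere table contains approximate
centromere-gap midpoints, which is sufficient for arm assignment at megabase
windows.

## Windowed copy number

Reads are binned into fixed windows (default 1 Mbp; the terminal window of
each chromosome may be shorter). Windows whose overlap with a user-supplied
blacklist exceeds a threshold (default 0.5) are masked and excluded from
binning, normalization and DLRS. Counts are scaled to full-window *density*
— a partial terminal window has proportionally fewer reads purely by
geometry — and normalized so that the median unmasked window sits at the
configured ploidy:

$$\widehat{CN}_i = P \cdot \frac{c_i / w_i}{\mathrm{median}_j (c_j / w_j)}$$

with $P$ the ploidy (default 2), $c_i$ the window count and $w_i$ the window
width relative to the window size. Median normalization assumes at least
half the genome is at the baseline ploidy; no ploidy inference is attempted
(a known limitation for grossly aneuploid genomes — configurable ploidy is
the escape hatch), and no GC or mappability correction is applied (the
generator injects no GC bias, and hooks would be speculative).

## Segmentation

Profiles are segmented per chromosome by penalized least squares: minimize
the within-segment weighted squared error plus a penalty per changepoint,
solved exactly by an $O(n^2)$ dynamic program (chromosomes have at most ~250
megabase windows, so exact DP is cheap). Windows are weighted by their width
relative to the window size — 1 everywhere except terminal partial windows.
This matters: a few-kilobase residual window rests on a handful of
amplification fragments, and with unweighted least squares its noisy CN
estimate regularly splits into a spurious single-window gain or loss; weight
proportional to width (hence roughly inverse to estimator variance) removes
these artifacts while leaving the regular grid ordinary least squares. Ties
in the DP objective are broken toward fewer segments.

The default penalty is BIC-like, $2\hat\sigma^2\log n$, with $\hat\sigma$
estimated robustly from the MAD of successive window differences (divided by
$\sqrt 2$). Segment levels are width-weighted means; integer CN is the level
rounded (half-to-even, R's convention) and clamped to $[0, 20]$; states are
gain/loss/neutral relative to the ploidy.

Arm-level events require a consistent direction over at least 80% of an
arm's usable windows (the source observations report arm events
qualitatively, so the fraction is an explicit package choice, configurable).
Genes take the integer CN of the segment containing their midpoint —
midpoint rather than any-overlap for determinism on boundary-straddling
genes; genes whose midpoint falls in a masked window are no-calls.

# The QC battery

Gates run in order; a cell failing the GII gate is not sequencing-eligible,
so downstream gates are reported as not applicable. Each discarded cell has
exactly one first-failing gate.

* **GII** (genome integrity index): the number of diagnostic PCR bands
  visible on the WGA QC gel, 0–4; at least 2 is required for sequencing.
  Band presence is an *input* (no gel-image processing).
* **Mapped reads**: at least 200,000 mapped reads. The sources state the
  bound both as "a minimum of" and "greater than" 200,000; the inclusive
  reading is implemented and the threshold is configurable.
* **DLRS** (derivative log ratio spread): on a seeded uniform subsample of
  200,000 mapped reads, binned at 1 Mbp and normalized at ploidy 2,
  $\mathrm{DLRS} = \mathrm{sd}\!\left(\mathrm{diff}(\log_2(CN/2))/\sqrt 2\right)$
  with differences taken within chromosomes only (cross-chromosome junctions
  are biologically meaningless and would inflate the statistic). Sample
  (n−1) standard deviation is used. Windows with zero CN are excluded
  (log of zero; at 200k reads over ~3,000 windows a zero count indicates
  dropout, not signal) and their number is reported. For i.i.d. log-ratio
  noise of sd $\sigma$, differencing doubles the variance and the $\sqrt 2$
  restores it, so DLRS estimates $\sigma$; it is invariant to rescaling all
  copy numbers. Cells with DLRS > 0.35 are discarded.
* **R50**: on a seeded 200,000-read subsample, fragments of origin are
  sorted by read count; $N_1$ is the smallest number of top fragments
  accumulating half the subsample, $N_2$ the number of fragments with any
  read, and $R50 = 100\,N_1/N_2$. A uniform library gives ~50; one dominant
  fragment gives $100/N_2$ — low values mean poor library complexity. The
  published verbal definition of R50 is ambiguous; this reading is the one
  consistent with "low values indicate poor complexity" and is an
  interpretation, not established fact. No discard threshold is published,
  so the gate is report-only unless a threshold is configured.

Subsampling seeds are recorded in the QC report so any run is reproducible.

# The synthetic-data generator

The generator produces the statistical structure the analysis assumes, so
every stage is testable without downloads. It emulates an Ampli1-style WGA
library:

1. **Truth profile**: baseline ploidy plus non-overlapping integer-CN
   events. Windows straddling an event boundary take the CN of the
   plurality overlap. The canonical scenario is the patient-like CTC: 1q
   gain (CN 3), 5q loss (CN 1), and a 2 Mbp CN-6 amplicon on 8q emulating a
   Myc-like amplification; the matched "white blood cell" is the same
   genome with no events.
2. **Fragment library**: chromosomes are partitioned into contiguous
   fragments with geometric lengths (a restriction-digest proxy), every
   base covered exactly once. Default mean fragment length is 10 kb — a
   desk-scale choice giving ~3×10^5 fragments genome-wide and ~100 per
   megabase window; real restriction digests are finer, which would only
   reduce fragment-sampling noise. Four fragments on four different
   chromosomes are designated QC loci (toy genomes with fewer than four
   chromosomes fall back to four distinct fragments).
3. **WGA bias**: each fragment drops out independently with probability
   `dropoutRate`; retained fragments get weight
   $CN \times e^{N(0,\sigma_a^2)}$. Lognormal per-fragment efficiency ×
   Bernoulli dropout is the standard minimal model for PCR-based WGA bias —
   the sources report the noise phenomenology (degradation-driven high
   DLRS) but no generative model, so the defaults
   (`amplificationSd = 0.3`, `dropoutRate = 0.1`) are package choices
   exposed in configuration, not field-derived values. GII band presence
   *is* the not-dropped status of the four QC loci, binarized exactly as
   the GII definition requires.
4. **Reads**: the unmapped (contaminating) count is binomial in
   `contaminationFrac` — contamination affects the mapped-read gate, not
   the CN profile, matching how a failed run with >500k sequenced but
   ~150k mapped reads is interpreted. Mapped reads are multinomial over
   fragments with probability proportional to *template mass* (weight ×
   fragment length), positions uniform within the fragment. The length
   factor matters: with weight alone, window read rates would track
   fragment count rather than base-pair extent, and the noiseless limit
   (dropout 0, $\sigma_a$ 0, contamination 0, many reads) would not
   converge to the truth CN; with template mass it converges exactly.
   Fragment-of-origin labels are retained for R50. Read length is
   irrelevant to binning and fixed nominally at 150 bp for SAM emission
   only.

All generators are pure functions of (parameters, seed).

What the generator does *not* emulate: GC/mappability bias, sequence
content and sequencing error, paired ends, doublets, and structural events
smaller than the fragment scale. Passing tests therefore demonstrate
correctness of the computation under the stated noise model, not robustness
to every artifact of real single-cell libraries.

# Numerical choices and degenerate inputs

* Zero-weight libraries (every fragment dropped or deleted) are an invalid
  state for read generation; all-zero or majority-zero window counts are
  invalid states for normalization, with distinct messages.
* DLRS requires at least 3 usable windows and 2 within-chromosome
  differences; otherwise the metric is reported undefined and the DLRS gate
  fails with that reason.
* R50 without fragment labels is reported unavailable and its gate skipped.
* The segmentation penalty floor is $10^{-8}$ when the robust noise
  estimate is zero (noiseless profiles), which keeps constant profiles at
  one segment per chromosome while still splitting true steps.
* Pipeline runs isolate per-cell failures: a malformed input produces an
  errored row in the cohort summary, not an aborted cohort.

# Problem sizes used in the test suite

The packaged tests run the full female genome (23 chromosomes, ~3,053
megabase windows) for the end-to-end recovery checks — ten tumor/normal
pairs at 500,000 reads each — and small 1–5 chromosome toy genomes
elsewhere; the whole suite completes in well under a minute on one core.
Brute-force oracles (exhaustive changepoint enumeration, literal DLRS
formula, binomial closed forms for GII dropout) back the corresponding unit
tests at sizes where enumeration is exact.
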