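# sclpCNV

Copy-number profiling and quality control for **single-cell low-pass
whole-genome sequencing** of whole-genome-amplified (WGA) cells — the data
produced when rare cells such as circulating tumor cells (CTCs) are isolated
one at a time, amplified with a PCR-based WGA kit, and sequenced shallowly
for copy-number variation (CNV) analysis. The package is aimed at analysts
who have *mapped read positions* per cell (SAM/BAM or a plain positions
table) and want an open, reproducible route from reads to per-window copy
numbers, segments, arm-level and gene-level calls, together with the
cell-filtering battery used to gate such libraries.

## What it computes

With windows $i = 1,\dots,n$ (1 Mbp by default) tiling an hg19-like genome
model, window counts $c_i$ and widths $w_i$:

* **Copy number**
  $\widehat{CN}_i = P \cdot \dfrac{c_i/w_i}{\mathrm{median}_j(c_j/w_j)}$ at
  fixed ploidy $P$ (default 2), after removing reads on alternative contigs
  and in blacklisted (masked) windows.
* **Segments** by exact penalized least-squares changepoint dynamic
  programming per chromosome (width-weighted; BIC-like default penalty
  $2\hat\sigma^2\log n$), rounded to integer CN with gain/loss/neutral
  states, plus arm-level calls (≥80% of an arm altered in one direction)
  and gene-level status by segment at the gene midpoint.
* **QC gates**, in order:
  * GII — genome integrity index, the number (0–4) of diagnostic WGA QC
    bands present; ≥2 required for sequencing eligibility;
  * mapped reads ≥ 200,000;
  * DLRS — derivative log ratio spread on a seeded 200,000-read subsample,
    $\mathrm{sd}\!\left(\mathrm{diff}(\log_2(CN/2))/\sqrt2\right)$ within
    chromosomes; cells with DLRS > 0.35 are discarded;
  * R50 — library complexity: percentage of detected amplification
    fragments needed to account for half the subsample (report-only by
    default).
* **Synthetic cells** — a first-class generator of Ampli1-style libraries
  (restriction-fragment tiling, lognormal amplification bias, fragment
  dropout driving the GII, unmapped contamination) over ground-truth CN
  profiles, so the whole pipeline is testable end to end without external
  data.

See `vignettes/low-pass-cnv-methods.Rmd` for the models, assumptions and
parameter rationale.

## Worked example

Simulate a patient-like CTC — arm-level 1q gain (CN 3), arm-level 5q loss
(CN 1), and a focal CN-6 amplicon on 8q — at 500,000 reads on the female
hg19-like genome, then QC and profile it:

```r
library(sclpCNV)

genome <- hg19GenomeModel("female")       # 22 autosomes + X
grid   <- buildWindowGrid(genome, 1e6)    # 3,053 windows

cell <- simulateCell(genome, patientScenarioEvents(genome),
                     nReads = 5e5, dropoutRate = 0.05,
                     amplificationSd = 0.2, seed = 11)

evaluateCell(cell@reads, grid, giiBands(cell@library), seed = 11)
#> QCReport: mapped=500000 GII=4 DLRS=0.199 R50=27.61 -> keep

profile <- callCNVProfile(cell@reads, grid)
profile
#> CopyNumberProfile: 3053 windows, 29 segments (1 loss / 24 neutral / 4 gain), ploidy 2

subset(callArmEvents(profile), state != "none")
#>    chrom arm nWindows gainFraction lossFraction fraction state
#> 2   chr1   q      125            1            0        1  gain
#> 10  chr5   q      133            0            1        1  loss

annotateGenes(profile, data.frame(chrom = "chr8", start = 126.4e6,
                                  end = 126.6e6, gene = "MYC_LIKE"))
#>       gene chrom  midpoint cn state
#> 1 MYC_LIKE  chr8 126500000  6  gain
```

Reading the output: the cell passes all four gates (all QC bands present so
GII = 4; half a million mapped reads; DLRS 0.199 is well under the 0.35
noisiness bar; R50 of 27.6% is an unremarkable complexity for a WGA
library). The profile recovers both simulated arm events with the full arm
altered (fraction 1.0), and the gene placed inside the simulated amplicon is
called at CN 6, a gain. A matched normal simulated with no events yields
zero non-neutral segments at the same settings.

Cohort runs (`runPipeline`) evaluate each cell's gates in order, profile
only the kept cells, record exactly one first-failing gate per discarded
cell, and write per-cell TSV/JSON outputs plus a cohort summary. A thin
command-line wrapper for simulate/qc/call lives in `inst/scripts/sclp.R`.

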