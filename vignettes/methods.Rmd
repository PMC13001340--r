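---
title: "Methods: collapsed-array occupancy, FISH histogram statistics, and the cell-cycle expression model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapsed-array occupancy, FISH histogram statistics, and the cell-cycle expression model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonetools)
```

This vignette documents the models and procedures implemented in
`histonetools`, the assumptions behind them, the tunable parameters and
their defaults, and the limitations of the synthetic data that drives the
test suite.

## The mapping problem and the collapsed reference

The *Drosophila* replication-dependent histone genes sit in a tandem
array of roughly 100 head-to-tail copies of a 5,080-bp repeat unit. Short
reads from the array cannot be assigned to an individual copy, and the
locus is only partially assembled in reference genomes: the printed
reference interval (chr2L:21,400,839–21,573,418, 1-based inclusive,
172,580 bp) is far shorter than the 508,000 bp a complete 100-copy array
would occupy. `build_collapsed_reference()` therefore excises that
interval and appends one consensus repeat unit as its own 5,080-bp
chromosome. Copy number is a free parameter recorded on the assembly and
is *never* inferred from the excised span, precisely because the native
span is under-assembled.

`project_fragments()` makes explicit what aligning to such an assembly
does implicitly: a fragment wholly inside the (simulated, fully expanded)
array maps to consensus offset `(position − array_start) mod L`.
Fragments spanning the junction between adjacent copies are wrapped
around the consensus end — the repeat is head-to-tail, so an aligner
would place such reads across concatenated copies; the consensus is
treated as circular for projection. Wrapping is switchable
(`wrap = FALSE` drops junction fragments with a counter); it is this
package's explicit stance, since reference-mapping behaviour at the
consensus ends is otherwise undefined. Fragments straddling the array's
*outer* boundary have no unambiguous collapsed location and are dropped
and counted. All printed coordinates are 1-based inclusive
(genome-browser dialect); internal fragment coordinates are 0-based
half-open, converted only at the I/O boundary.

## Coverage, CPM, and per-gene-copy normalization

`compute_coverage()` piles fragments into per-base depth (run-length
encoded via IRanges) and stores the *mean* per-base depth per fixed-size
bin (default 2 bp), the coverage-track convention; the trailing partial
bin is averaged over its actual width, so total signal mass
(`value × bin width`) conserves projected bases exactly. CPM is
counts-per-million-*mapped-fragments*: every value is multiplied by
`1e6 / total`, where a wrapped fragment counts once regardless of how
many pieces it projected in. HGC normalization then divides the
consensus chromosome — and only it — by the copy number, exactly. The
state machine is strict (`raw → CPM → HGC`), so a track always knows
what its numbers mean. Blacklist masking sets any bin overlapping a
blacklist interval to `NA` (any-overlap at bin resolution: conservative
exclusion); masked bins are excluded from every downstream sum and
ranking.

## Genome-wide bin scan and gene matrices

`bin_scan()` tiles each chromosome from coordinate 0 with
non-overlapping bins of the repeat-unit size (5,080 bp), sums the signal
mass in each (no length normalization — the statistic is a sum), and
ranks descending with minimum-rank ties. Trailing partial bins are
retained and flagged rather than discarded, since dropping them would
silently lose terminal genes. `manhattan_table()` lays the scan on a
cumulative coordinate in assembly order with the consensus chromosome
last, labelling the top-k bins.

`gene_matrix()` builds scale-regions matrices: 500-bp flanks at fixed
resolution plus the gene body linearly rescaled to 2,000 bp, aggregated
into 10-bp columns (50 + 200 + 50 columns; the column width is this
package's choice — the underlying matrix resolution is not otherwise
determined). Column values are exact fractional-base integrals of the
piecewise-constant track, so a constant track yields exactly constant
rows for any gene length, and minus-strand rows are reversed so every
row reads TSS→TES. Rows are sorted by descending total signal.
`cluster_rows()` uses agglomerative hierarchical clustering with Ward
linkage (`ward.D2`) on Euclidean row distances, cut at `k = 3` by
default. The clustering tool flag the procedure mirrors does not name
its linkage; Ward/Euclidean is recorded here prominently as an
assumption of this package.

## RNA-FISH histogram statistics

`sum_projection()` sums a z-window of `round(window / z_step)` slices
(default 1.8 µm) centered on a chosen slice. `intensity_histogram()`
counts pixels per integer intensity value over a declared range (bin
size fixed at 1), with defaults 0–699 for the H3/H2a probes and 0–1399
for H1/CDS; pixels above the range are clipped into the top bin with a
warning (whether out-of-range pixels should be clipped or discarded is
underdetermined; clipping preserves the pixel count). All bins are
retained. Skewness is the moment estimator `g1 = m3 / m2^(3/2)` over the
pixel sample implied by the histogram — without small-sample bias
correction, since pixel counts are 10^4–10^6 and the correction factor
is negligible at that size. The `q`-th percentile bin is the smallest
bin whose cumulative pixel fraction reaches `q/100` (a verbal
convention made precise here). The field size is configurable; the
default is a 100 µm × 100 µm field (a stated "100 µm²" image area is
ambiguous between an area and a side length; the default takes the
square field and is configurable either way).

Genotype comparisons use a two-sided **exact Mann–Whitney U test**
implemented by exhaustive enumeration of all `choose(n1+n2, n1)` group
assignments (pooled sizes ≤ 16), which remains exact under ties via
midranks — something the usual exact algorithms do not provide — with
`p = min(1, 2·min(P(U′ ≤ U), P(U′ ≥ U)))`, and Benjamini–Hochberg
adjustment across the probe sets submitted together. Larger samples fall
back to the tie-corrected normal approximation. Log-scale mean curves
use `log10(mean + 1)`: high bins contain zeros and the pseudocount
handling is this package's choice.

## Cell-class statistics and ΔΔCt

`class_counts()` evaluates an arbitrary boolean expression over per-cell
labels per embryo, against either all counted cells or a caller-stated
denominator class. `group_test()` provides two-tailed unpaired
(equal-variance), Welch, and paired t-tests with BH adjustment across
whatever family of comparisons is submitted in one call — family
boundaries are caller-controlled, since no universal convention exists
for how single-panel comparisons group into an adjustment family. A
paired comparison whose differences are all zero is degenerate; it is
reported as p = 1 with a warning rather than an error, because synthetic
fixtures can legitimately produce it.

`ddct()` implements Livak relative quantification: technical replicates
averaged per (gene, genotype, biological replicate); ΔCt against the
reference gene within each replicate; ΔΔCt against the mean control-
genotype ΔCt; `log2FC = −ΔΔCt` (the standard orientation, stated
explicitly since plotted fold changes do not always declare their sign
convention) and `fold = 2^(−ΔΔCt)`.

## The area-under-the-curve expression model

`cycle_phase_model()` represents per-cell transcription as a
piecewise-constant rate over cell-cycle phases with durations summing
to 1. The per-cycle mRNA output is the exact closed form
`Σ rate(phase) × duration(phase)`; per-embryo totals scale linearly with
cell count, so bulk log2 fold changes reduce to per-cell area ratios.
mRNA decay is omitted by default — the model is a pure area under the
curve — with an optional first-order decay constant exposed (default 0).
The default durations are the condensed S–G2–M cycle of the embryonic
ventral nerve cord (`d_G1 = 0, d_S = 0.3, d_G2 = 0.5, d_M = 0.2`); the
G2:M split within the condensed cycle is this package's choice of a
plausible embryonic partition, and every identity the tests assert is
algebraic in the durations rather than dependent on these particular
values. The numeric parameterizations are illustrative: the model's
purpose is the qualitative reconciliation (equal areas for
reduced-output genes, elevated bulk for full-output genes under one
phase setting), not a fit to measured fold changes.

## The synthetic-data generators

All generators hang off one global seed; each stage derives a sub-seed
as a hash of `(seed, stage label)` (`derive_seed()`), so stages rerun
independently and reproducibly.

**Genomes and fragments.** `simulate_genome()` expands the array
interval into exactly C head-to-tail unit copies — an idealization of
the true array, deliberately different from the under-assembled native
span. Fragment start positions follow a per-bp weight model (background
everywhere, ×E inside the array, ×fold in optional off-target peaks),
sampled exactly in two stages (multinomial over constant-weight
segments, then uniform within the segment). Fragment lengths are
Normal(150, 30) truncated to [50, 700] bp — typical short paired-end
chromatin-profiling inserts under a 700-bp alignment bound; the true
insert distribution of the emulated libraries is not described anywhere,
so this is a stated default, not an estimate.

**Image fields.** `simulate_vnc_stack()` places cells on a jittered grid
(guaranteed packable; requesting more cells than grid positions is an
error), assigns phases from the phase-fraction vector, and renders
cytoplasmic signal as an annulus around each nucleus — the quantified
statistics use whole-field pixels, so sub-cellular realism beyond
"cytoplasmic ring" is unnecessary. In wildtype mode only S-phase cells
express, at per-probe maximal summed intensity `M_g`; in mutant mode
S, G2 and M cells express at `f_g·M_g`, with defaults `f = 1` for
H3/H2a and `f = 0.5` for H1/CDS, matching the observed direction
structure (reduced maximal output for H1-class probes only). Intensities
are integer-quantized so unit-bin histograms are exact. Defaults: 250
cells of radius 2.8 µm (nucleus 0.4 of the radius) in a 100-µm field at
0.4 µm/pixel, background Normal(20, 5) per slice, signal CV 0.15. With
these densities the expressing annuli cover ≈15% of the field in
wildtype mode — enough that the 90th-percentile pixel falls inside the
signal band rather than the background, which is what makes the
percentile statistic informative. The tests render the same physical
field at 0.8 µm/pixel with 225 cells and 6 slices to keep runtimes
short; fractions, intensities and statistics are resolution-invariant.

What the image simulator does **not** emulate: optics (no PSF,
deconvolution, or z-attenuation), nuclear morphology, nascent HLB foci
(off by default), segmentation error, or spatial expression gradients.
Passing tests therefore demonstrate the correctness of the measurement
pipeline and the direction structure of the phase/output model — not
robustness to microscope artefacts.

**Cell tables and Ct tables.** `simulate_cell_table()` derives boolean
labels from the simulated phase (EdU = S, pH3S10 = M, CycB = G2/M;
cytoplasmic FISH per genotype mode), so EdU-positive cells always carry
FISH signal — the co-occurrence constraint observed in the annotated
data — and neural markers are drawn with a genotype-specific
co-occurrence probability. `simulate_ct_table()` writes
`Ct = baseline − log2(expression) + loading offset + noise`, with the
loading offset shared by all genes of a biological replicate (it cancels
in ΔCt) and the reference gene held at fold change 0, so ΔΔCt inverts
the construction exactly at zero noise.

## Numerical choices and degenerate inputs

* Scan ties share the minimum rank; partial trailing bins are flagged,
  not dropped.
* Gene-body resampling integrates the piecewise-constant track with
  fractional-base precision (no nearest-bin rounding).
* Zero-variance histograms (a single occupied bin) make skewness
  undefined and raise an error rather than returning NaN.
* `NA` (masked) track bins poison any scan bin or matrix column that
  overlaps them, and masked scan bins are excluded from ranking.
* Empty fragment sets are valid inputs everywhere (N = 0 is a request,
  not an error); negative enrichments, malformed intervals and unknown
  chromosomes fail fast.

## Problem sizes used by the checks

The test suite and acceptance script use: a 3 × ~1 Mb genome with a
100 × 5080 bp array and 10^6 fragments for enrichment recovery; a
genome whose collapsed chromosomes tile exactly into 161 scan bins (100
seeds each for detection at E = 50 and null calibration at E = 1, the
latter at 2 × 10^5 fragments); 400-gene matrices over 20 seeds for the
clustering property; 20 seed families of 5 + 5 image fields for the FISH
direction checks; and 100 seeds for the ΔΔCt bias check. These sizes
were chosen so that every stochastic property is tested at meaningful
power while the whole suite stays desk-scale.

## Known limitations

* The projection module assumes identical repeat copies; diverged copies
  and alignment ambiguity at copy boundaries are out of scope.
* The expanded simulated array is an idealization; no attempt is made to
  model the partially assembled native locus structure.
* The exact Mann–Whitney enumerates up to pooled size 16; beyond that
  the tie-corrected normal approximation applies.
* The area-under-the-curve model is deliberately decay-free and
  steady-state; it is a bookkeeping identity, not a kinetic model.
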