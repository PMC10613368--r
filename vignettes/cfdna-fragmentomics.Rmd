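---
title: "Models and methods: cfDNA fragmentomics at desk scale"
author: "cfFragmentomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cfDNA fragmentomics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfFragmentomics)
```

# Scope

cfFragmentomics measures the fragmentation signatures of cell-free DNA
(cfDNA) from aligned paired-end reads: fragment sizes and their
sub-modal structure, nucleosome and transcription-factor footprints in
depth, terminal sequence motifs, the repeat context of fragment ends,
and circular-DNA content reconstructed from split reads. Because the
signals of interest are properties of a *population* of fragments, the
package also ships a generative model of such populations — a
simulator with complete per-fragment ground truth — so that every
detector can be validated end to end at desk scale. This vignette
records the models, the parameter choices and their rationale, the
numerical decisions, and what the simulation-based validation does and
does not establish.

# Fragment reconstruction and the hybrid size metric

Fragments are reconstructed from concordant read pairs: same contig,
opposite orientations, nonzero template length. The fragment interval
runs from the leftmost mate start to the rightmost aligned mate end;
the interval lives in a `GRanges` (1-based, closed), with BED and SAM
conventions converted at the boundary so that all half-open interval
semantics (a fragment ending where a blacklist interval begins does
not overlap it) are preserved.

Short inserts are the critical case. With overlap-trimming of adapter
read-through, a fragment shorter than the read length *R* = 150 yields
two identical-length mates whose read length *is* the fragment length,
while soft-clipping can corrupt the aligned insert size. The hybrid
metric therefore uses the read-1 length whenever it is below *R*, and
|TLEN| otherwise; a full-length read with TLEN 0 has no knowable size
and is excluded. Read 1 (not the min or max of the mates) drives the
branch: under trimming both mates are equal-length for the sub-*R*
case, so the choice only matters for malformed input, where it is at
least deterministic.

Blacklist filtering removes fragments with ≥ 1 bp overlap — the
conservative reading, since no overlap fraction is standard — and is
applied at fragment level: if either mate of a pair overlaps the
excluded region, the whole fragment does.

# The synthetic scenarios

The simulator emulates three biological conditions as size mixtures:

| component | form | plasma_like | proliferative | apoptotic |
|---|---|---|---|---|
| nucleosomal ladder | peaks at mode − 10·k, k = 0..6, geometric weights 0.6ᵏ, Gaussian jitter sd 1.5 bp | mode 167 bp | mode 155 bp | mode 155 bp (145 variant selectable) |
| short component | weight | 0.05 | 0.45 | 0.05 |
| short form | — | Laplace at 53 bp, scale 5 bp | piecewise exponential, rates 0.010/0.055 per bp, kink 118 bp, support 30–400 bp | same piecewise exponential |
| mitochondrial | uniform 30–100 bp, no oscillation | 0.02 | 0 | 0 |

The modes (167; 145/155), the 10 bp period, the 53 bp minor peak, the
118 bp kink and the 150 bp read length are the study conditions the
scenarios are built to reproduce. The remaining numbers are the
package's own choices, fixed once: the geometric ladder decay 0.6 and
jitter sd 1.5 bp give the clean multi-peak combs seen in healthy
plasma; the Laplace scale 5 bp keeps the 53 bp single-stranded-library
peak narrow, as published ssDNA-library profiles show; the
pre/post-kink rates 0.010/0.055 make the post-kink decay steep relative
to the plateau-like pre-kink region, which is what "the slope changed
steeply" describes; the 45 % short weight makes short fragments the
dominant feature of the proliferative state without erasing the
nucleosomal ladder.

Placement is uniform over a 2 Mb random nuclear contig (16.5 kb
mitochondrial contig for mito fragments) except for two planted
effects. First, short-component 5′ ends are re-weighted into repeat
intervals (default for the proliferative scenario: Simple_repeat and
Satellite at 4× their base-fraction odds), emulating the
NFR-specific repeat-end enrichment of proliferating cells. Second, in
the proliferative scenario each short fragment is, with probability
0.7, snapped to the nearest genomic position whose first three
reference bases at the 5′ terminus equal the planted 3-mer
(default `TAT`). Snapping — rather than overwriting read bases — keeps
read and reference identical, so downstream motif extraction from the
reference is exact. The planted 3-mer is a stand-in chosen to be
mirror-symmetric (equal to its own reversal); an odd-length k-mer
cannot be a reverse-complement palindrome, so mirror symmetry is the
operative sense of "palindromic" for 3 bp end motifs, and the flag
reported by `topKmer` tests exactly that.

Circles are planted as intervals avoiding the blacklist and
tandem-duplication tracks. Micro-circle sizes are drawn from Gaussians
at 202 and 349 bp (sd 3) with weights 0.6/0.4 — the first peak
dominant, as in published microDNA spectra; making the ranking
deterministic also makes the peak order reproducible. Before
"excision", the 4 bases at the circle start are copied to just past
the circle end, giving every junction the direct-repeat
(microhomology) context characteristic of microDNA. Junction reads are
sampled across the circle origin with both split segments ≥ 20 bp and
emitted as one primary plus one supplementary record with reciprocal
`SA` tags — the representation a split-read circle detector consumes.
Junction reads are unpaired; pairing them would add records without
adding evidence, since the detector operates per query name.

The emitter writes SAM text directly (the simulator knows the true
origin, so no aligner is needed): sub-150 bp fragments produce
fully-overlapping mates whose SEQ length equals the fragment size,
longer fragments produce 150 bp mates with |TLEN| = fragment size,
both orientations occur with probability 0.5, and 2 % of fragments
carry MAPQ 20 (below the coverage filter) with the rest at 60.

What the simulator does **not** emulate: sequencing errors, PCR
duplicates, GC and mappability bias, soft-clipping of linear reads,
real genome repeat structure, or inter-sample biological variance.
Passing the recovery suites therefore demonstrates that the
measurement code is correct and unbiased under clean conditions — not
that it is robust to artifacts real data would add upstream
(alignment, duplicate marking and trimming are consumed as given).

# Numerical choices

**Peak finding.** Histograms are smoothed with a 5 bp centered moving
average; local maxima are computed plateau-aware (a run of equal
smoothed values reports its center — smoothing an isolated spike
produces exactly such a plateau), filtered at prominence ≥ 5 % of the
range maximum, and thinned to a minimum 5 bp separation, tallest
first. The separation suppresses twin maxima that sparse histograms
(e.g. a few hundred circle lengths) produce 1–3 bp apart, while
staying below the 10 bp nucleosomal period so ladder peaks remain
separable.

**Periodicity.** Counts in the 100–160 bp window are detrended by a
21 bp moving average (wide enough to remove the envelope, narrow
enough to keep the 10 bp comb), and the autocorrelation argmax over
lags 6–15 bp is reported. The detection floor on the peak
autocorrelation is 0.4: under aperiodic (Poisson or uniform) count
noise the maximum over these ten lags has its 95th–99th percentile
near 0.30–0.38, while genuine 10 bp combs score around 0.6, so 0.4
rejects ≥ 99 % of nulls with a wide margin to true signal.

**Slope change.** The NFR/NBR boundary is estimated by fitting a
continuous two-segment linear model to log10(count + 1) against size
over 60–160 bp, with an exhaustive breakpoint search minimizing SSE
and quality 1 − SSE₂seg/SSE₁seg. The fit operates on the trailing
11 bp running-minimum envelope of the histogram rather than the raw
counts: the nucleosomal comb contributes order-of-magnitude periodic
excursions over 95–160 bp that otherwise dominate the least-squares
fit (empirically dragging the breakpoint to the ladder mode), whereas
the envelope — the minimum over one full period ending at each size —
tracks the sub-nucleosomal baseline in which the kink lives. A
trailing (not centered) window is used because for a decaying baseline
the trailing minimum equals the baseline at the window's right edge,
leaving the breakpoint location unbiased. Quality below ~0.2 indicates
no real slope change (single-exponential histograms land there in
median). The package ships 118 bp as the fixed classification default,
with the detector as the reproducible surrogate for re-deriving it.

**Footprints.** Coverage is fragment-level (each fragment increments
every bin it overlaps, once): fragments, not reads, carry the
protection signal, and fully-overlapping mates would otherwise double
count. This differs at bin edges from read-level once-per-bin counting
(as deepTools does); the two are not claimed equivalent. Flanks of
1000 bp and 100 body bins resolve 10 bp-bin nucleosome oscillation;
anchors overrunning contig edges are dropped, not padded. BPM
normalization conserves a genome-wide sum of 10⁶ and makes region
matrices invariant to library size.

**End motifs.** Windows span the breakpoint with 5 bp outside and
5 bp inside (the figure convention spans the break; no window size is
standard, so both are configurable). Reference sequence is used on
both sides — outside context does not exist in the read — and windows
are N-padded at contig edges, with N excluded from that column's
count. Information content is 2 + Σf·log₂f bits per column, bounded
[0, 2]. Sampling is without replacement, clamped with a warning when
fewer fragments exist than requested (default 5,000,000, the
depth-normalization count).

**Repeat ends.** Both fragment termini are counted, each once — the
per-fragment reading of "end positions near the 5′ end", equivalent to
the 5′ ends of both mates; strand-aware single-end modes are retained
for sensitivity analysis. The right terminus point is end − 1 (the
last covered base) so containment under half-open intervals is well
defined. Overlapping repeat annotations resolve to the interval with
the smaller start, ties to the longer — rare in practice and
deterministic. Genome-expected proportions are base fractions of
per-class merged intervals (the natural reading of "proportion of
repeats in the genome").

**Circles.** Junction evidence requires exactly one primary and one
supplementary alignment on the same contig and strand with the
genomically-downstream segment first in the (reference-oriented)
query; because SAM stores sequence and CIGAR in reference orientation,
this rule is strand-invariant as written. Clustering is single-linkage
with both breakpoints within 5 bp and ≥ 2 supporting reads (the
upstream tool's thresholds are unpublished; 2 is the minimum giving
corroboration), call coordinates are per-cluster median breakpoints,
and microhomology is the longest exact prefix match between the
sequences starting at the circle start and just past the circle end.
Length spectra default to per-call weighting (each circle once);
per-read weighting is available since the original weighting is
unstated. Discordant-pair evidence is not required: split reads
suffice in simulation and carry the breakpoint at base resolution.

**Statistics.** Welch's t (via `t.test`, unequal variances) with
explicit handling of zero-variance degeneracies; pairwise Welch tests
with Bonferroni (`p.adjust`); PCA via `prcomp` with zero-variance
features dropped and a fixed sign convention (largest-magnitude
loading positive per component) so scores are reproducible.
Significance tiers follow the usual 0.05/0.01/0.001/0.0001 legend.

# Open design points, resolved

* One global 118 bp threshold is applied to all sample types; the
  plasma-style distributions give it no special support, but a single
  cutoff keeps NFR/NBR classes comparable across conditions.
* The pipeline orchestrator (`runPipeline`) derives per-stage seeds
  from the run seed by a fixed rule (seed × 1000 + stage index), so a
  single integer reproduces a run byte for byte; the manifest lists
  every output with its MD5.
* The package is a library: the exported functions and `runPipeline`
  are the interface, and `scripts/acceptance.R` is the reproducible
  end-to-end entry point.

# Problem sizes

The validation suites run the scenarios at 200,000 fragments (size
structure, periodicity, slope change — matching the scale at which the
mixture's features are printed), 30,000–60,000 fragments for motif and
repeat recovery, and 200 planted circles with mean 5 junction reads.
These sizes put Monte-Carlo error well inside the asserted tolerances
(e.g. the 118 bp breakpoint within ±2 bp) while keeping a full test
run in the low minutes on one CPU.

# Known limitations

* The slope-change estimator carries a few-bp variance at 200k
  fragments (occasional +2–4 bp excursions across seeds); it localizes
  a corner in a noisy envelope, and the quality score should accompany
  any reported threshold.
* Coverage vectors are dense per contig; genomes far beyond the
  packaged 2 Mb scale would want run-length or sparse bins.
* The circle caller consumes split alignments as given; it does not
  realign, so breakpoint accuracy is bounded by the aligner's clipping
  in real data.
* Welch tests on 3-replicate groups have limited power; the planted
  2× enrichment power check reflects the study's replicate structure,
  not a general guarantee.
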