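# cfFragmentomics

Multidimensional fragmentomic analysis of cell-free DNA (cfDNA) from
paired-end whole-genome sequencing of single-stranded libraries, with a
deterministic read simulator that provides per-fragment ground truth for
every analysis stage.

cfDNA released by dying and proliferating cells carries the imprint of
the chromatin it came from: fragment sizes cluster at the
mononucleosomal ~167 bp with a 10 bp sub-modal oscillation, coverage
dips and peaks trace the footprints of nucleosomes and transcription
factors, the nucleotides flanking each fragment end record the nuclease
that cut it, and a fraction of fragments derives from extrachromosomal
circular DNA (eccDNA/microDNA). This package implements the full
measurement stack for these signals — for researchers studying cfDNA
biology in vitro (e.g. organoid culture media) or benchmarking
liquid-biopsy fragmentomic pipelines — plus a simulator that emulates
the relevant fragment populations so each detector can be validated
against a known truth.

## What it computes

* **Hybrid fragment sizing.** For a concordant read pair the fragment
  size is the read length when read 1 is shorter than the platform read
  length *R* (overlap-trimmed mates carry the whole fragment), and the
  absolute insert size |TLEN| otherwise:

  size = len(r1) if len(r1) < R, else |TLEN|

* **Size-distribution structure.** Integer histograms per origin
  (nuclear vs mitochondrial); peak calling on the smoothed histogram
  with prominence and separation control; sub-modal periodicity by
  detrended autocorrelation (argmax lag in 6–15 bp); and the
  short-fragment slope-change threshold from an exhaustive-breakpoint
  two-segment linear fit to log10(count + 1) of the histogram's
  running-minimum envelope. Fragments at or below the threshold
  (default 118 bp) form the nucleosome-free-region (NFR) class,
  larger ones the nucleosome-bound-region (NBR) class.

* **Protein footprints.** Fragment-level coverage in 10 bp bins,
  normalized to bins per million (BPM: bin × 10⁶ / total, the TPM
  analogue), meta-profiles around point anchors (TSS, TFBS) and across
  scaled region bodies (transcription units, super-enhancers), and a
  sample × region matrix for PCA ordination.

* **End motifs.** Uniform sampling of up to 5,000,000 fragments,
  breakpoint-spanning windows (5 bp outside + 5 bp inside each
  terminus, orientation-aware), position frequency matrices with
  per-column information content in bits, and top terminal k-mer with a
  mirror-palindrome flag.

* **Repeat-end attribution.** Fragment termini as width-1 points,
  annotated against a RepeatMasker-style track (half-open containment,
  deterministic tie-breaks), compared with genome-expected base
  fractions, and tested between NFR/NBR replicate groups with Welch's
  t.

* **Circular DNA.** Junction evidence from primary + supplementary
  split alignments (downstream segment first in the query ⇒ circle end
  ligated to circle start), single-linkage clustering of breakpoints
  (±5 bp, ≥2 reads), tandem-duplication masking, length spectra with
  microDNA peaks, junction flank motifs and direct-repeat
  microhomology, and depth-normalized abundance (supporting reads per
  million mapped).

* **Statistics.** Welch's t with Welch–Satterthwaite df, pairwise t
  with Bonferroni correction, and sign-stabilized PCA.

The simulator (`buildReference`, `scenarioConfig`, `simulateScenario`)
generates a 2 Mb nuclear + 16.5 kb mitochondrial reference with
annotation tracks (repeats with literal tandem sequences, TSS/TU/TFBS,
super-enhancers, blacklist, tandem duplications), three scenario
presets (`plasma_like`, `proliferative`, `apoptotic`), planted circles
with junction-spanning split reads, and SAM output whose pairing
semantics match the sizing rule exactly.

## Worked example

```r
library(cfFragmentomics)

cfg  <- scenarioConfig("proliferative", nFragments = 50000L, seed = 7L)
sim  <- simulateScenario(cfg, tempdir())
aln  <- readAlignments(sim$paths$sam)
frags <- pairFragments(aln)
frags <- filterFragments(frags, sim$reference$tracks$blacklist)
#> 1263 fragment(s) removed by blacklist, 0 additional by MAPQ < 0
frags
#> FragmentSet with 48737 fragments (48737 nuclear, 0 mito; mito contig 'chrM')
#>   size range: 30-284 bp

prof <- sizeHistogram(frags, "nuclear")
sc   <- detectSlopeChange(prof)
sc$threshold; round(sc$quality, 2)
#> 121
#> 0.72

cls <- classifyFragments(frags, threshold = 118L)
length(cls$nfr); length(cls$nbr)
#> 22307
#> 26430

tk <- topKmer(extractFlanks(sim$reference, cls$nfr))
tk$kmer; round(tk$frequency, 2); tk$mirrorPalindromic
#> "TAT"
#> 0.62
#> TRUE
```

The slope-change detector localizes the planted short-fragment kink
(118 bp; here 121 at n = 50,000 — within a few bp, converging at larger
n), the 118 bp cutoff splits the population into 22,307 NFR and 26,430
NBR fragments, and the NFR 5′ termini are dominated by the planted
mirror-symmetric 3-mer at close to its planting probability.

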