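---
title: "Quantifying G-quadruplex replication obstacles: models, parameters and design choices"
author: "g4pombe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying G-quadruplex replication obstacles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4pombe)
```

# Scope

g4pombe implements the computational core of a study of how stabilized
G-quadruplex (G4) structures impede DNA replication in fission yeast: G4
motif prediction on genomic sequence, the peak/feature enrichment accounting
used to interpret Cdc20 (Pol epsilon) ChIP-seq under a G4-stabilizing ligand
(PhenDC3), single-molecule quantification of DNA damage on stretched DNA
molecules, and the closed-form assay formulas (fiber tract statistics,
doubling time, helicase unwinding, circular-dichroism normalization,
qPCR-stop relative amplification). A synthetic-data module generates every
input with coordinate-level ground truth, so the whole pipeline runs and is
tested offline. Read-level processing (trimming, alignment, peak calling,
the IDR model itself) is out of scope: the pipeline consumes scored peak
lists and published peak counts.

# G4 motif model

A motif is four tracts of at least `min_tract` consecutive guanines
(default 3, the number of stacked tetrads) separated by loops of 1-25
nucleotides. The scanner reports leftmost non-overlapping matches per
strand, scanning each strand 5'->3'; the minus strand is scanned on the
reverse complement and mapped back to forward 0-based half-open
coordinates. Three conventions needed fixing because motif counts are
convention-sensitive:

* **Tracts are maximal G-runs.** A run of 12 guanines is one tract, never
  tract-loop-tract. This keeps the tetrad interpretation literal and makes
  counts stable.
* **Loops are matched minimally, with backtracking.** At each step the
  nearest eligible next tract is tried first, but the search backtracks, so
  a match is reported whenever any chain of four tracts with admissible
  loops exists. (With the default loop minimum of 1 the greedy choice can
  always be extended, but backtracking keeps the scanner correct for any
  parameterization.)
* **Opposite-strand motifs are reported independently and never merged**;
  the enrichment tables count motifs, and no merge rule is defined for
  them.

`min_tract = 2` gives the two-tetrad mode used to discuss the weaker
quadruplexes on the non-transcribed strand of 5S rDNA genes. `N` is allowed
inside loops but never inside tracts. Every emitted motif re-validates
against its own grammar on construction, and the test suite checks
coordinate identity against an independently written character-level
brute-force matcher on a thousand random sequences.

The polymerase stall site is annotated one nucleotide 5' of the first
G-tract in motif-strand orientation (`start - 1` for plus, `end` for minus,
0-based), the position where primer extension halts at a folded quadruplex;
a motif abutting the sequence boundary gets a flagged missing value. Whether
"first tract" should instead be counted in template order is not decidable
from a primer-extension gel, so the choice is documented rather than
hidden.

# Enrichment accounting

The ledger reproduces the shape of the study's per-condition tables: peak
count, total bp covered (union length, overlaps counted once), mean peak
length (`round(bp / n)`), GC% of the covered bases (N excluded from the
denominator), and two overlap counts per feature class — peaks overlapping
at least one feature, and features overlapping at least one peak, both at
>= 1 bp overlap ("within" in the tables is used interchangeably with
"overlapped with", so containment is not required). Fold changes
(treated/mock) are computed on bp coverage and on the features-within-peaks
counts; values are kept unrounded internally and printed
half-away-from-zero to 2 decimals with trailing zeros trimmed, which is
exactly how the published cells round (e.g. 16/7 prints 2.29, 6/5 prints
1.2). Peak sets are used as given (no pre-merge) for counts; union only for
coverage and GC.

Replicate reliability uses the pseudo-replicate ratio: reads pooled and
split into two pseudo-replicates give `Np` reproducible peaks against `Nt`
from the true replicates; `Np/Nt` within a factor of 2 — read symmetrically
as 0.5 <= ratio <= 2, which both published ratios (1.53, 0.95) satisfy —
flags reliable replicates. Since peak calling is out of scope the ratio
consumes externally produced counts.

```{r ledger}
ledger_from_counts(
  n_peaks = c(344, 568), bp_covered = c(464876, 752369),
  feature_counts = list(g4 = c(50, 96), trna = c(44, 58), rrna5s = c(7, 16)))
```

# Single-molecule damage imaging

The imaging module quantifies fluorescent "dots" of labeled DNA damage
along stretched molecules: trace backbones in the YOYO-1 channel, detect
dots in the damage channel, assign dots to molecules, and report dots/um
converted to dots/Mbp with the stretched-DNA constant of 3000 bp/um.

**Tracing.** The backbone channel is smoothed (sigma 1 px) and thresholded
at median + 5 robust SDs (MAD). A histogram-valley threshold like Otsu's is
the textbook default but collapses here: molecules occupy under ~3% of the
frame, and with that class imbalance the Otsu objective is minimized inside
the background mode (measured on rendered fields: it returned roughly the
background median and masked 44% of the frame). The noise-adaptive
threshold is also invariant to constant intensity offsets. The mask is
skeletonized with Guo-Hall two-subiteration thinning — chosen over
Zhang-Suen, whose deletion rules remove 2-px diagonal staircases and
measurably shorten diagonal molecules — and each skeleton component's
longest path (double breadth-first search) becomes the molecule trace,
which implicitly prunes short side branches. The path is smoothed with a
5-px moving average before arc-length measurement because a raw
8-connected chain overestimates length by up to ~8% depending on
orientation, and each end is extended along its local direction while
still on foreground (the medial axis stops about half a line-width short
of a blunt tip). Molecules shorter than 5 um are discarded to avoid
quantization noise. Crossing molecules are not split at junctions; at the
default field density crossings are rare and mostly cancel in pooled rates
(both the lost branch length and its dots drop out). This is the known
limitation of the tracer.

**Dot detection.** Difference of Gaussians at the expected PSF sigma (1.2
px vs 1.6x), local maxima above `k = 5` robust SDs of the band-passed
image, 3x3 centroid refinement to sub-pixel precision.

**Quantification.** Dots assign to the nearest trace within 3 px;
farther dots count as off-molecule background and are excluded but
reported. The pooled rate is total dots / total length — robust to short
molecules — rather than the mean of per-molecule ratios; both are emitted
because the original analysis software does not state which it used.
Because two dots closer than the detector's resolution merge into a single
local maximum, the raw pooled ratio undercounts at high density (measured
on rendered fields: ~14% of dots lost at 90 dots/Mbp versus ~3% at 30).
The summary therefore also carries a declumping-corrected rate: modelling
dot positions along the fiber as a 1D Poisson process of intensity lambda,
detected clusters have density lambda e^(-lambda r) at resolution distance
r (3 px, the same proximity scale used for assignment), which is inverted
for lambda. Condition summaries use the corrected rate by default and the
raw ratio on request.
Condition summaries report mean +/- SD of pooled dots/Mbp across replicate
fields and a two-sided Welch t-test against the control (Welch rather than
the equal-variance test, as the safer default when the published analysis
says only "t-test"); two identical zero-variance groups report p = 1
explicitly.

# Synthetic data: what it emulates, and what it does not

Each generator is a pure function of one configuration object (`sim_config`),
seed included; identical configurations give identical outputs, and all
truth records use the same types the analysis emits.

* **Genomes.** Background sequence at a configurable GC fraction (default
  0.36, fission-yeast-like) is rejection-sampled until it contains no
  scanner match on either strand; motifs built from the configured tract
  and loop ranges (A/T loops) are planted at non-overlapping positions,
  half per strand, with one-base non-G/non-C buffers, and the finished
  genome is verified to scan to exactly the planted set. Scanning a planted
  genome must therefore give recall = precision = 1 — this is the
  generator's contract, not an empirical observation about real genomes.
* **Peak experiments.** Two conditions x two replicates, 400 true peaks per
  condition; a mock peak centers on a feature with odds 0.05, a treated
  peak with `feature_enrichment` times those odds (default 2). Deliberate
  placements draw features without replacement and background placements
  avoid features, so the planted odds are exact: chance overlaps would
  otherwise add the same background count to both conditions and pull the
  observable fold toward 1 at fission-yeast gene density. The base odds are
  kept small so odds ~ probability and the expected features-within-peaks
  fold equals the configured odds ratio. Replicates share a configurable
  fraction of true peaks (default 0.8) and fill up with non-reproducible
  background peaks; scores decay with placement noise.
* **Fiber fields.** Near-straight molecules (random-walk headings, turns
  uniform within +/-5 degrees per 10 px step; the 15-degree bound is a hard
  cap — sharper wiggles fall below the diffraction limit, get smoothed away
  by the PSF, and would make the measurable contour length disagree with
  the recorded truth). Lengths are normal (15 +/- 5 um), rendered as
  unit-density lines convolved with a Gaussian PSF (sigma 1.2 px) at
  signal-to-noise 5 over Gaussian background noise, in 2048 px square
  frames at 0.16 um/px — a pixel scale typical of the EMCCD setups used for
  this kind of imaging; the original study does not state its
  magnification, so this is a documented assumption, and it is
  configurable. Dot counts per molecule are Poisson with mean
  `rate x length_um x 3000e-6` (default 30 dots/Mbp; 3x for the treated
  condition, matching the reported ~3-fold damage increase at 50 uM
  PhenDC3), placed uniformly along the molecule with 0.5 px jitter.
* **Tract samples.** Zero-truncated normal tract lengths in kb, converted
  to um at 2 kb/um; defaults reproduce the study design (n = 17 control at
  60 +/- 15 kb vs n = 50 treated at 40 +/- 15 kb, a one-third reduction).
  The published distribution is right-skewed but no model is stated; the
  truncated normal is the minimal choice with the right support.

What passing tests on these data do **not** show: robustness to uneven
illumination, stage drift, stitching artifacts, clumped or overlapping
fibers, non-Poisson (clustered) damage, mappability and copy-number biases
in peak placement, or real peak-caller score distributions. The generators
establish that the estimators are correct under the stated statistical
model, not that the model exhausts real data.

# Numerical choices and degenerate inputs

Rounding of reported ratios is half-away-from-zero (R's own `round` is
round-half-even, which would print 1.625 as 1.62 but 2.285 as 2.28 and
break agreement with the published cells). Mean peak lengths round to
integers. The Mann-Whitney comparison uses the exact distribution for small
tie-free samples and the tie-corrected normal approximation otherwise, as
R's `wilcox.test` chooses. Empty or flat images trace to an empty molecule
list rather than an error; zero-damage fields report rate 0. Degenerate
zero-variance condition comparisons report p = 1. Malformed BED input is
rejected with the offending line number, never coerced.

# Problem sizes

The test suite and the acceptance script run everything at the sizes the
analyses are designed around: 1000 random 5-kb sequences for the
scanner/oracle comparison, 10 seeds x 400 peaks per condition for the
enrichment recovery, 20 fields of 200 molecules (2048 px frames) for the
damage-rate recovery plus two triplicate conditions for the fold
comparison, and 100 simulated repetitions of the n = 17/50 fiber design.
These sizes keep Monte-Carlo error well inside the stated tolerances.
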