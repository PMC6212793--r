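---
title: "Counting CRISPR-induced DNA damage foci and measuring the checkpoint response"
author: "dsbFoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting CRISPR-induced DNA damage foci and measuring the checkpoint response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbFoci)
```

## The problem

Timed activation of Cas9 with guide RNAs that hit 1–17 homologous genomic
sites turns break number into a controlled experimental variable: each
cut target allele becomes one DNA damage focus (γH2AX, 53BP1) visible in
fixed-cell microscopy, and the cell-cycle consequences of a defined number
of double-strand breaks can then be read out per cell with FUCCI
live-cell imaging. This package implements the quantitative machinery
around that design: the foci-counting image analysis, the expected-break
arithmetic, live-focus retention metrics, cumulative cell-cycle-entry
statistics, micronucleation fold changes, and the classification of indel
spectra into repair pathways. Because the underlying measurements are
wet-lab ones, every analysis component is paired with a seeded synthetic
generator so that each estimator can be validated by parameter recovery:
simulate data with known truth, run the full analysis, and check that the
configured truth comes back.

## Fixed-cell foci counting

Nuclei are detected on the DAPI channel by thresholding the
median-filtered signal and separating touching nuclei with a watershed
(`segmentNuclei()`). The median filter uses a square window clipped at
the image edge (`medianSmooth()`); the threshold is Otsu's by default,
with a fixed-threshold override for reproducible tests. The watershed
runs on the Gaussian-smoothed distance transform of the foreground
(smoothing sigma 1 px by default); components below `minNucleusArea`
(200 px) are discarded as debris and labels are relabelled contiguously
as 4-connected sets. The threshold method and the watershed construction
are implementation decisions — the originating protocol names only
"thresholding" and "watershed".

Foci are called per nucleus on the marker channel after background
subtraction with a Difference of Gaussians (`dogFilter()`, sigmas 2 and
6 px, reflective boundaries). A candidate pixel must exceed the nucleus
background centre by `foldK` (default 2) times the background standard
deviation *and* exceed an absolute minimum; candidate regions grouped by
8-connectivity are kept only if strictly larger than `minFocusArea`
(default 16 px, so a 16-px region is rejected). The background centre is
the per-nucleus median of the filtered signal and the background SD its
MAD-based robust standard deviation (1.4826 × MAD); the SD entering the
criterion is the image-wide median of the per-nucleus SDs by default,
with the per-nucleus alternative exposed as `perNucleusSd` because the
protocol wording admits both readings.

Two numerical choices deserve emphasis:

* **The absolute minimum defaults to the extranuclear noise ceiling**
  (the maximum of the filtered signal outside all nuclei). A DoG-filtered
  image has spatially correlated background, with coherence area of
  order πσ²; percentile-based minima (e.g. the 95th percentile) leave a
  5% tail whose pixels cluster into connected regions that regularly
  pass the 16-px area criterion, producing spurious foci. No real focus
  should be dimmer than anything the cell-free background produces, so
  the ceiling is the principled default. It is recomputed per image and
  can always be overridden with `absMin`.
* **A diffuse nuclear marker level interacts with the DoG filter.** If
  the marker channel carries a bright nuclear plateau, the band-pass
  filter produces an overshoot ring just inside the nuclear rim; this is
  exactly the kind of artifact the user-defined absolute minimum exists
  to suppress, and it must then be tuned per experiment (as the original
  protocol tunes its parameters "by manually comparing"). The generator
  therefore defaults to a flat marker background
  (`markerNucleusLevel = 0`); when you simulate a diffuse level, supply
  a correspondingly raised `absMin`.

## What the generator emulates — and what it does not

`generateField()` renders axis-aligned elliptical nuclei (axis ratio at
most 1.5) with Gaussian-smoothed edges on a dark background, plants
isotropic Gaussian foci (sigma 2.2 px, chosen so a focus covers at least
20 px above half-maximum and comfortably clears the 16-px criterion),
and applies Poisson shot noise plus Gaussian read noise (sd 20 a.u.).
A configurable fraction of nuclei is placed as touching pairs at centre
distance 1.2–1.6 times the mean radius to exercise the watershed;
touching nuclei are rendered with a ~2 px dim seam at the contact, as
the apposed nuclear envelopes appear in real DAPI images. Without that
seam, a deeply overlapped pair of ellipses elongated along their common
axis is geometrically a single convex blob that no distance-transform
watershed could split — real images always carry the intensity cue.

Planted foci respect a minimum centroid separation (default 16 px).
This spacing is dictated by the detection physics, not by the renderer:
the DoG(2, 6) response of a sigma-2.2 spot has its zero crossing near
r ≈ 5.9 px, so spots closer than about 12 px merge into a single
adjacent-pixel region under the calling criteria, exactly as crowded
foci merge in real images. Recovery tests are therefore meaningful only
in the resolvable regime; at 16 px separation merged regions cannot
occur and the planted count is the correct expectation.

The generator does not emulate photobleaching, stage drift, 3D optics,
camera-specific noise, chromatin texture, or nucleoli; passing recovery
tests demonstrates that the estimators are calibrated on data satisfying
their stated assumptions, not that real microscopes hold no further
surprises. Default nucleus radii in the fixed-cell suites (60–80 px)
correspond to epithelial nuclei at a 60×, ~0.11 µm/px configuration.

## Break numbers: kinetics, expectation, simulation

The per-allele cut probability over time is a lagged saturating
exponential (`cutFraction()`): 0 up to `tLag`, then
`pMax (1 − exp(−(t − tLag)/tau))`. The functional form is a modelling
choice; its anchors are that breaks become detectable around 2 h, and
that roughly half of all target alleles are cut around 8 h. The defaults
`tLag = 2` h, `pMax = 1` and `tau = 6/log(2) ≈ 8.66` h encode exactly
those anchors — `cutFraction(8)` is 0.5 by construction.

Expected foci per nucleus (`expectedFoci()`) are then
`background + nSites × (fG1·2 + fG2·4) × cutFraction(t)`: G1 cells carry
two copies of every target site, G2 cells four, and control nuclei show
about three background foci, assumed additive with the induced breaks.
The default phase mix (80% G1 / 20% G2) is a stated assumption for an
asynchronous culture. `simulateBreakEvents()` realises the same model
per allele on a discrete time grid (each allele cut at most once, cut
times distributed per the kinetics, exponential repair lifetimes), and
`mcConcurrentFoci()` counts cut-but-unrepaired breaks; with repair
disabled it agrees with the closed form within Monte-Carlo error, which
the test suite asserts at 10,000 cells.

Repair lifetimes are exponential with mean 1 h for irradiation-induced
breaks (an assumption; the absolute value is not printed in the source
material) and mean 3 h for Cas9-induced breaks — the 2 h difference is
the quantity of interest, reflecting slower repair of nuclease-induced
breaks. Retention of a tracked focus is frames × interval with no
interpolation (a single-frame appearance retains one interval), so a
lifetime maps to its frame-count rounded up; at a 0.5 h interval the
expected retention difference between the default cohorts is 1.99 h.

## Tracking

`linkFoci()` links per-frame detections by greedy nearest-neighbour
assignment (closest admissible pair first; ties broken by lower
detection then track index) with a hard displacement gate and no gap
closing — a focus that blinks off for one frame terminates its track.
This is deliberately the simplest defensible rule: the source protocol
does not describe its linking, and gap closing would complicate the
retention convention without changing the cohort comparisons the
package makes.

## Cell-cycle entry statistics

`simulateTracks()` draws one row per cell: phase at damage, the time of
its next transition (S entry for G1 cells, M entry for G2 cells),
censoring at the horizon, and micronucleation for dividing cells. Times
are hours post-transfection. The baseline transition time is
Uniform(8, 20) h and the horizon 32 h, so that entry, quantified from
`t0 = 8` h as in the source experiments, completes within the 24 h
observation window for undamaged cohorts; the absolute baseline is not
printed in the source and Uniform over the window is the least-committed
choice that reproduces the published curve shapes. Damaged G2 cells add
a Uniform(4, 6) h checkpoint delay (the printed "about 4–6 h"), scaled
by 0.2 under checkpoint abrogation ("drastically shortened", no number
printed). A fraction of damaged G1 cells (default 0.2, from the printed
~20% S-entry reduction) arrests; arrest preferentially hits early-G1
cells because cells past the restriction point no longer arrest, and
spills over to late-G1 cells only when the requested fraction exceeds
the early pool, so the overall arrest fraction is always honoured.
Micronucleation probabilities per division are 0.02 (intact checkpoint)
versus 0.10 (abrogated): the absolute baseline is not printed, the pair
embodies the printed 5-fold increase.

`cumulativeEntry()` keeps censored cells in the denominator — the
published cumulative plots imply this convention. The delay estimator is
the 50% quantile-crossing shift with linear interpolation
(`delayAtQuantile()`); when a curve never reaches the quantile the
result is explicitly "not estimable", never 0. `reductionAt()` is the
relative entry deficit at a time point, `micronucleationFold()` the
frequency ratio with a Fisher exact test (a zero control count yields a
one-sided lower bound rather than infinity), and `groupCompare()`
provides Welch t-tests and one-way ANOVA with Bonferroni-adjusted
all-pairs comparisons (Bonferroni, not Holm, because that is the
procedure named alongside the source figures). Curves are pooled across
fields/experiments; per-experiment analysis is available by calling the
estimators per subset.

## Indel classification

`classifyIndels()` partitions an indel-size spectrum into the small
indels characteristic of non-homologous end joining (+1, +2, −1, −2,
−3, −4), resection-dependent deletions (−5 and deeper), and a
remainder. Unedited reads (size 0) are reported separately and excluded
from the `*_repair_fraction` denominators, because the ~30% NHEJ share
refers to repair products, not to all reads. The default generator
mixture places 0.30 on the NHEJ classes and 0.70 on resection products
(−5, −8).

## Problem sizes and reproducibility

All generators are pure functions of `(spec, seed)`; `runPipeline()`
threads one seed through every stochastic stage and reproduces its
outputs bit-identically. The validation suites run at the cohort scales
of the underlying study where those are stated — 150 cells per arm for
entry curves (three experiments of at least 50 cells), 2,000 divisions
per arm for micronucleation, 10,000 cells for Monte-Carlo/closed-form
agreement, 100,000 reads for spectra, 100–200 seeded fields for the
image suites — and the oracle-equivalence suite checks `detectFoci()`
against a literal pixel-by-pixel implementation of the calling criteria
on 64×64 fields. At 2,000 divisions and an intact-arm probability of
0.02 the micronucleation fold carries ~17% relative standard error;
tests therefore compare it on the log scale within three standard
errors rather than pretending tighter precision.

## Known limitations

* The cutting model is phenomenological; it reproduces the onset,
  half-cut and saturation anchors but no mechanistic Cas9 kinetics.
* Per-allele cutting is treated as independent; sister-chromatid
  correlation in G2 would change focus-count variance (not the mean).
* Foci closer than the DoG resolution limit merge, as in real data;
  counts are calibrated only in the resolvable regime.
* The tracker has no gap closing and no nucleus-motion registration; it
  is intended for sparse, slow-moving foci.
* Curves assume a single cohort observed on one clock; mixed
  populations with unknown damage times need external alignment.
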