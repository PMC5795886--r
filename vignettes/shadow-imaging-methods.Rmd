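---
title: "Methods: lens-free shadow-image cell analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lens-free shadow-image cell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadowcount)
```

## The measurement principle

In lens-free shadow imaging a thin sample chamber rests directly on a bare
CMOS sensor under a quasi-point illumination source. Each cell casts a
radially structured diffraction footprint — a dark zero-order core
surrounded by a bright first-order ring — whose size tracks the cell's
diameter and whose contrast tracks its optical density. Two facts make the
modality quantitative without reagents:

* the lens-free field of view is the whole sensor (24.4 mm² for a
  5.70 mm × 4.28 mm sensor), so one frame averages over far more cells
  than a 1 mm² hemocytometer grid square, suppressing sampling variance;
* dead cells flatten as their membranes rupture, attenuating light less,
  so their shadows show up to ~3.54× the peak-to-peak contrast of live
  cells — a separation large enough to classify viability from a single
  intensity feature, with no trypan blue.

`shadowcount` implements the full analysis chain for such images along
with a synthetic twin of the imaging physics sufficient to validate every
stage.

## The analysis chain and its assumptions

**Adaptive binarization.** The image is partitioned into a 4 × 4 grid of
areas (remainder rows/columns are absorbed by the last tile so exactly 16
areas always result). Each area's threshold is its mean intensity minus a
per-cell-line gray offset, clamped to [0, 255]. We give each area its own
threshold rather than deriving one global value: tiling only has a purpose
if it compensates the gentle illumination roll-off of the bare-sensor
light path. Pixels *strictly below* the threshold become candidates;
equality maps to background, the conservative choice (fewer false
candidates). Shadow polarity is assumed dark-on-light, consistent with
threshold = mean − offset. Sentinel states (candidate 96, cluster 175,
center 60, background 255) live in a separate label plane, never
overwriting raw intensities — a raw pixel may legitimately equal a
sentinel value, and the viability stage needs the untouched image.

**Matrix-expansion clustering.** Candidates are scanned in raster order;
each seeds a 3 × 3 matrix whose candidate members are absorbed and seed
further matrices until nothing expands. Chaining 3 × 3 windows is exactly
the transitive closure of 8-adjacency, so clusters coincide with the
8-connected components of the candidate mask; the test suite enforces that
equivalence against an independent graph-components oracle on random
fixtures. Clusters are reported in raster order of their seed pixel, which
fixes detection order and makes the whole chain deterministic.

**Size rules.** With bounding box h × w (pixels):

| condition | class | yield |
|---|---|---|
| h ≤ 20 and w ≤ 20 | singlet | 1 cell |
| otherwise, box fits in 20 × 40 either orientation | doublet | 2 cells |
| otherwise | noise | 0 cells |

The 20-px constants are empirical for this sensor geometry and are
configurable. The doublet rule is applied symmetrically in orientation
(cell pairs have no preferred axis); it tests the bounding box only, with
no fill-ratio criterion. Clumps and islands need no extra rule — they
simply exceed the noise bound. Border-touching clusters are clipped, not
excluded.

**Center marking.** A singlet's center is the floor midpoint of its box
(ties toward top-left). A doublet gets two centers at the floor quarter
points of its long axis — the centers of the two overlapping 20-px boxes
laid over the pair — each reported with its half of the box. Note the two
conventions differ at even sizes (midpoint `(n-1)/2` vs quarter `n/4`,
both floored); both are arbitrary one-pixel choices and are frozen by
tests.

**PPD viability.** Each cell's peak-to-peak distance is max − min
intensity over the 11 × 11 window centered on its marked center (not
re-centered on the local extremum), computed on the raw image. Windows at
borders are clipped, never padded — padding would fabricate intensities
into the extrema. A cell is dead iff PPD ≥ the per-cell-line viability
constant; the tie goes to dead, an arbitrary but fixed convention. No
canonical gray offsets or viability constants exist for any cell line —
both are empirical instrument calibrations. `calibrate_ppd_threshold()`
is provided as a convenience that midpoints the live/dead PPD modes of a
labeled (or well-separated unlabeled) sample; it is a bootstrap aid, not
an instrument constant.

**Reporting.** Viability defaults to (total − dead)/total × 100. The
historical formula (live − dead)/live × 100 is retained behind
`mode = "as_printed"`: it gives 0 % for a half-dead sample that standard
usage calls "50 % viable" and can go negative, so it is not the default,
but both are shipped because instruments in the field print the latter.
Concentration supports hemocytometer mode (mean grid count × 10,000 ×
dilution) and area–volume mode (count / (FOV area × chamber depth) × 1000
× dilution). No canonical chamber depth exists; the 0.1 mm default is a
typical counting-chamber depth and is explicitly illustrative. ER and CV
follow the standard summed-series and sample-SD (n − 1) definitions.

## The synthetic scene generator

The generator is the fixture engine: it renders scenes whose ground truth
is known exactly, so recovery can be scored.

**What it emulates.** A cell's patch is a parametric radial profile
`-cos(πr/r_c)·exp(-r/2r_c)` tapered smoothly to zero at twice the core
radius, scaled so the patch's max − min equals the requested amplitude to
within quantization: a dark zero-order core, a bright first-order ring,
controlled contrast. Dead cells use 3.54× the live amplitude. Defaults:
2.2 µm pixel pitch (1/2.5-in 5-Mpx sensor class), 1944 × 2592 frame,
background 200, live amplitude 55 — the largest value whose 3.54× dead
counterpart still fits the 8-bit range around that background without
clipping given the profile's ~0.75/0.25 dip/ring split — cell diameters
5–80 µm, Gaussian read noise with σ = 2 counts. Debris is rendered small
(2–4 px) at 0.3× live amplitude, below any sensible binarization offset.
Clumps are rendered as broad featureless dark blobs (super-Gaussian
falloff, 35–55 px) rather than scaled-up single-cell patterns: an extended
opaque mass shows no clean Airy structure, and a naively scaled bright
ring would distort the 16-area means enough to create artifacts that say
nothing about the algorithm. Objects are placed by rejection sampling with
centers at least (d₁+d₂)/2 + 3 px apart; exceeding the achievable density
raises a capacity error. Everything is reproducible from a single seed.

**What it does not emulate.** No physical Fresnel propagation (the
analysis consumes only contrast and footprint), no z-distance or
wavelength dependence of polarity and ring structure, no optical
aberrations, overlapping cells, motion blur, or illumination gradients
beyond what the 16-tile scheme absorbs. Passing recovery tests therefore
demonstrates the correctness of the algorithmic chain under the stated
phenomenology, not performance on real instrument captures.

**Dilution series.** A scene's expected occupancy is concentration × FOV
area × chamber depth / 1000. By default the realized count is
floor(λ) + Bernoulli(frac(λ)) rather than Poisson. This is deliberate: the
full-scale experiment images thousands of objects per frame, where Poisson
shot noise is a ~2 % effect and measured linearity is limited by the
counting chain itself; a 512 × 512 desk-scale twin holds only tens of
objects, where Poisson occupancy noise alone would dominate the regression
and mask exactly the property the series probes. The scaled-down twin
preserves the phenomenon under test, not the absolute counting statistics;
`count_mode = "poisson"` restores physical occupancy for anyone studying
the statistics themselves.

## Numerical conventions

* Coordinates are 1-based (row, col) from the top-left, matching R and
  the raster-scan order of the algorithm; file I/O preserves this.
* Multi-channel images collapse by the arithmetic channel mean, rounded
  half up (shadow images are monochrome; any fixed policy works). All
  rounding in I/O and rendering is half-up for cross-platform
  determinism, avoiding R's round-half-even.
* Inputs deeper than 8 bits are rejected unless explicitly downscaled
  (16-bit values divided by 257, rounded half up): every sentinel and
  threshold is defined on the 8-bit scale.
* Degenerate inputs: an empty candidate plane yields an empty cluster
  list; zero detected cells flags viability as undefined (`NA`) rather
  than inventing 0 or 100; CV requires n ≥ 2 and a nonzero mean; ER
  requires a positive reference sum.

## Problem sizes in the shipped tests

The test suite and the acceptance script run on 512 × 512 scenes (about
5 % of the full frame, holding 25–200 objects), 100 random 128 × 128
clustering fixtures, an exhaustive 1–45 px bounding-box sweep, and a
5-level × 3-replicate dilution series — sizes chosen so the whole suite
runs in well under a minute on one core while every rule still fires in
both directions. The recovery properties are stated for mid-size cells
(15–35 µm): at noise levels of a tenth of the live amplitude, the
binarization flicker band at a cell's shoulder widens with
amplitude/radius, so very large live cells (> 40 µm) can shed detached
one-pixel satellite candidates. That is an inherent trait of hard
per-pixel thresholding, shared by the modeled instrument, and the reason
per-cell-line offsets are calibrated empirically.

## Known limitations

* Clusters of more than two attached cells are discarded as noise, never
  split; sub-pixel centroids are out of scope.
* The doublet rule cannot distinguish a genuine pair from an elongated
  noise streak of the same box size (no fill-ratio test is defined).
* PPD is evaluated at the marked center; if the marked center falls off
  the pattern extremum (e.g. for a clipped border cluster), the PPD is
  attenuated.
* All constants (gray offset, viability constant, the 20/40/11 px
  geometry) are per-instrument, per-cell-line calibrations; the package
  ships the machinery, not the constants.
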