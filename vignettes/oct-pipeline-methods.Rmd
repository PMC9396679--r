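---
title: "From spectral fringes to vascular maps: methods behind octapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spectral fringes to vascular maps: methods behind octapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octapipe)
```

## Overview

`octapipe` implements the post-processing chain of a swept-source OCT
(SS-OCT) retinal imaging system with angiography: spectral-fringe
reconstruction, BM-scan registration and averaging, axial volume alignment,
B-scan flattening, graph-cut segmentation of the two outer retinal
boundaries with thickness statistics, and speckle-variance OCT angiography
(SV-OCTA) with en face slab projections. The modelled acquisition raster
covers 360 B-scan positions, each scanned three times (BM scans = 3, i.e.
1080 B-scan frames), 360 A-scans per B-scan and 1024 depth pixels, at a
100 kHz sweep rate — a whole volume in about four seconds.

Because no raw in vivo data accompany the method, the package ships a
synthetic retinal phantom with complete ground truth. Every stage is
validated against that truth; the phantom is therefore a first-class,
tested component, not a fixture.

## Reconstruction

A-scan reconstruction follows the fixed order: reference-spectrum (DC)
subtraction, analytic-signal formation (one-sided spectrum), dispersion
compensation by `exp(-i(c2*k^2 + c3*k^3))` with `k` the centred normalized
spectral coordinate, Hann windowing, FFT keeping the first `n_k/2`
magnitude bins, `20*log10(mag + eps)`, and an affine map of
`[floor_db, ceil_db]` onto `[0, 1]` with clipping.

Numerical choices:

* Magnitudes are normalized by the window sum, so a unit-amplitude on-bin
  reflector sits at 0 dB. The default display range is (-30, +60) dB — a
  declared default, configurable everywhere.
* The reference spectrum inside a volume is each frame's mean fringe over
  its A-scans. Per-frame (rather than global) referencing tolerates slow
  source drift and is identical on phantoms.
* Input fringes are assumed k-linear, as produced by a hardware k-clock;
  numerical resampling is out of scope.
* Dispersion coefficients default to zero; the phantom's fringe synthesis
  is dispersion-free unless a test injects a known phase.

The fringe synthesizer builds each A-line as a DC term plus
`sum_z sqrt(I(z)) cos(2*pi*z*k/n_k + phi_z)` with per-voxel phases drawn
once per volume. Random phases avoid coherent artifacts, but they make the
reconstructed A-line a coherent sum: adjacent voxels inside the window's
point spread interfere, producing genuine interference speckle even on a
"noiseless" phantom. Validation therefore compares reconstruction and
input at the reconstruction's native axial resolution (locally averaged
intensities over ~5 px) rather than voxel by voxel.

## Registration

Two corrections are applied, mirroring the two motions present in such
acquisitions:

1. **Interframe (BM) registration.** Repeat frames at one position are
   registered to the first frame by FFT phase correlation with local
   upsampled cross-power refinement (matrix-multiply DFT), default
   precision 0.1 px, then averaged.
2. **Inter-B-scan axial alignment.** Each averaged B-scan is collapsed to
   its mean axial profile; neighbouring profiles are registered by the
   integer lag maximizing circular normalized cross-correlation within
   ±`max_lag` (default 50 px), and offsets accumulate outward from a
   reference B-scan. The reference defaults to the location with maximal
   total intensity, a deterministic proxy for the "good-quality" frame an
   operator would choose manually. The 1-D collapse is deliberate: axial
   NCC on profiles is robust to lateral content change between adjacent
   B-scans; full 2-D registration between different positions would
   confuse anatomy with motion.

Circular shifts are used throughout (consistent with the flattening
stage), so alignment is a permutation of each A-line, not an
interpolation. One consequence worth knowing: genuine retinal curvature
also shifts the mean axial profile, so on a strongly curved volume the
axial "motion" estimate absorbs a slowly varying component of curvature.
Flattening downstream removes it either way.

## Flattening

Per B-scan: Gaussian blur (sigma 2 px), 3×3 median filter, thresholding
(Otsu by default) to zero noise above the surface, Canny edge detection,
then the first edge row per A-line scanning from the vitreous side. A 15-px
1-D median filter removes outlier columns; undetected columns are filled
by linear interpolation. Each A-line is then circularly shifted so the
detected surface lands on a common centre depth (default `n_depth/3`).
Kernel sizes and the threshold method are declared defaults — the
procedure is standard, the constants are tunable parameters.

The Canny detector (gradient by central differences on a
Gaussian-smoothed image, non-maximum suppression, hysteresis linking by
connected components) suppresses responses in the outermost pixel ring,
where finite differences see padding rather than tissue.

## Graph-cut segmentation

The ILM/NFL and RPE/BrM surfaces are found as exact minimizers of a
column-wise cost under hard smoothness constraints (default ±2 px between
4-adjacent columns), via minimum s-t cut on the standard optimal-surface
graph: one node per voxel, infinite downward intra-column arcs, smoothness
arcs between columns, and terminal arcs carrying the signed
weight-transformed costs. The cut is computed with `igraph`'s max-flow;
the construction guarantees the global optimum, which the test suite
verifies against an independent per-B-scan dynamic-programming oracle on
decoupled problems (smoothness along locations relaxed).

Cost design: after axial Gaussian smoothing (sigma 2 px), the ILM cost is
the negative *backward* axial difference (dark-to-bright going down) and
the RPE cost the *forward* difference (bright-to-dark). The asymmetric
pair makes each surface sit exactly on the first/last bright row of a
noiseless band — symmetric differences leave a half-pixel tie. The RPE
pass is restricted to at least `min_separation_px` (default 20 px) below
the found ILM by assigning forbidden voxels a cost exceeding any feasible
total, preserving exactness. A parabolic sub-pixel refinement exists
behind a flag and is off by default so the optimizer's exactness remains
testable.

Thickness is `(rpe - ilm) * axial_um_per_px`, with the mean and population
standard deviation over unmasked columns. No optic-nerve-head or pecten
exclusion is applied automatically; callers can mask columns.

## Speckle-variance angiography

Flow contrast is the interframe population variance over the N registered
repeats, computed on the log-grayscale structural frames (the displayed
images; N = 3 in the modelled acquisition). Log-domain variance is
essentially invariant to depth attenuation and reflectivity scale, which
is why the choroid remains detectable beneath the strongly attenuating
RPE; a linear-domain variance would weight vessels by squared brightness
and bury the choroid. No projection-artifact removal is applied.

Slabs resolve per column from the segmented surfaces: superficial
[ILM, ILM+25% of thickness), intermediate [+25%, +55%), deep [+55%, RPE),
choroid [RPE, RPE+60 px). Percent-of-thickness boundaries adapt across
species; the anatomy motivating them (NFL/GCL plexus, IPL borders,
INL–OPL bed, choriocapillaris) is qualitative, not numeric. Projections
are max-intensity by default for retinal slabs and mean for the choroid.
En face contrast enhancement is background subtraction (large-kernel
Gaussian) followed by percentile stretching.

## The phantom: what it emulates, and what it does not

The generator produces layered reflectivity (bright NFL, alternating
inner bands, bright RPE, attenuating choroid), parabolic curvature,
multiplicative speckle with exponential intensity statistics,
inter-B-scan axial motion as an integer random walk, and flow
decorrelation: static voxels share one speckle realization per location,
blended with per-frame independent draws at weight
`1 - static_frame_correlation`, while vessel voxels are redrawn fully
independently each frame. Species presets scale the retinal stack to the
measured mean thicknesses (mouse 210, rat 186, owl 260, opossum 138.5,
sturgeon 142 µm); per-layer fractions within the stack are *not*
species-calibrated — they reuse the default stack's proportions. The owl
preset hosts vessels only in the choroid (the avian retina is avascular),
modelled as a dense bed just below Bruch's membrane.

Two modelling choices deserve explanation:

* **Choroidal attenuation.** The choroid's reflectivity decays
  exponentially with depth (tau = 10 px), so the stack fades into the
  noise floor. Without it the phantom ends in a sharp artificial edge
  stronger than the RPE/BrM transition — an edge no real retina has, and
  one that would invalidate segmentation testing.
* **Speckle contrast 0.6.** Displayed log B-scans are not unit-contrast
  speckle: spatial oversampling and display processing compound roughly
  independent speckle cells, giving an effective contrast near
  `1/sqrt(3) ≈ 0.58`. The value also controls the deterministic pedestal
  that bounds the *relative* intensity fluctuation of static voxels whose
  shared speckle draw is near zero; at contrasts approaching 1 that tail
  becomes heavy enough to mimic flow, which display-processed SV-OCTA
  images do not show.

What the phantom does **not** model: optical point-spread and aberrations,
sensitivity roll-off, fringe washout, Doppler phase, projection artifacts
(flow shadows cast on deeper layers), pecten or hyaloid geometry, and eye
blinks or saccades beyond the axial random walk. Passing tests therefore
demonstrate correctness of the algorithms under controlled statistics;
they do not certify performance on in vivo data with those effects.

## Problem sizes and determinism

Validation runs use scaled-down rasters — typically 10–32 locations (180
for the axial-motion study), 32–64 A-scans and 256 depth pixels, against
the instrument's 360 × 3 × 360 × 1024 — chosen so the full suite and the
acceptance script complete comfortably on a single CPU while keeping
every per-column statistic well-sampled. All randomness flows from a
single seed; the generator restores the caller's RNG state, and repeated
runs are bit-identical.

## Known limitations

* Axial alignment absorbs slow curvature into its motion estimate (see
  above); offsets are meaningful relative to the reference, not absolute.
* The RPE pass of the segmentation assumes the ILM leaves at least
  `min_separation_px` of room inside the search band; degenerate bands
  are rejected rather than repaired.
* `EBImage::medianFilter` quantizes to 16-bit internally — irrelevant at
  display precision, but the flattening surface is integer-rounded anyway
  before the circular shift.
* The binary container is deliberately minimal (flat little-endian array
  plus YAML sidecar); DICOM and vendor formats are out of scope.
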