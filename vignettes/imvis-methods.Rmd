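---
title: "Methods: spheroid morphometry and the IMVIS viability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spheroid morphometry and the IMVIS viability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroVis)
```

# Scope

spheroVis quantifies drug response in tumor-spheroid screens run on agarose
microwell chips. Each chip chamber holds a row of circular wells with one
spheroid per well; each well is imaged in bright-field (whole-spheroid
outline), calcein AM fluorescence (live, esterase-active cells), and
optionally Hoechst (nuclei). The package covers image I/O and device
layouts, segmentation, Feret morphometry, binary-area-fraction (BAF)
viability readout, the combined IMVIS index, Mann–Whitney group statistics,
and a synthetic scene generator with exact ground truth for validation.

# The measurement model

## Diameter

A spheroid's size is summarized by its minimum and maximum Feret (caliper)
diameters on the segmented binary mask, combined as

$$D_{mean} = \frac{D_{min} + D_{max}}{2}.$$

`feretDiameters()` computes both via rotating calipers on the convex hull of
the pixel centers. Because a pixel is a unit square, not a point, one pixel
width is added to each caliper extent: a single pixel has diameter 1 px, a
run of $k$ pixels has length $k$ px. This keeps the digitized diameter of a
rasterized disk of radius $r$ at $2r + 1$ px, consistent with the
pixel-center rasterization convention used throughout (a pixel at 0-based
index $i$ sits at physical position $i \times \text{pixelSize}$).

## Binary area fraction

Viability within a calcein ROI is the fraction of ROI pixels strictly above
a fluorescence threshold:

$$\mathrm{BAF} = \frac{\#\{p \in \mathrm{ROI} : I(p) > T\}}{\#\mathrm{ROI}}.$$

The default threshold is $T = 100$ RFU on a 0–250 RFU display scale, i.e.
40% of the display maximum. `computeThreshold()` supports both an
`"absolute"` mode and a `"fraction_of_max"` mode (fraction of the bit
maximum or of the per-image maximum), so the same 100 RFU cut can be
expressed either way. The inequality is strict: a pixel exactly at the
threshold does not count as viable signal.

## IMVIS

The IMVIS index combines geometry and viability into a single volume-scaled
score:

$$V = \frac{4}{3}\pi\left(\frac{D_{mean}}{2}\right)^3, \qquad
  \mathrm{IMVIS} = V \times \mathrm{BAF}.$$

$V$ is in µm³, BAF is unitless, so IMVIS is an "equivalent viable volume"
in µm³. It is jointly monotone: larger spheroids and higher viable
fractions both raise the score, and either $D_{mean} = 0$ or
$\mathrm{BAF} = 0$ zeroes it. Treatment effects are reported as percent
change of the group-mean index versus the untreated control
(`percentChange()`).

# Segmentation

`segmentBrightfield()` and `segmentCalcein()` share a pipeline: Gaussian
smoothing (σ = 2 px, separable compiled convolution with replicate-edge
handling), a global threshold, hole filling, connected-component labelling
(EBImage), and a minimum-area filter (default: the area of a 50 µm disk,
which removes debris and satellite aggregates while keeping ≥200 µm
spheroids).

The global threshold differs by channel:

* **Bright-field** objects are dark on a bright background and the
  histogram is strongly bimodal, so Otsu's criterion is used directly.
* **Calcein** ROIs decay radially into a dark background; the histogram is
  a background spike plus a long foreground tail, where Otsu systematically
  cuts inside the object. We instead use a triangle threshold (maximum
  chord distance between the histogram and the peak-to-tail line) to get an
  initial split, then refine it to the half-height point
  $T = \tfrac{1}{2}\left(\mathrm{median}(I_{bg}) + Q_{0.25}(I_{fg})\right)$,
  where background/foreground come from the initial split. The 0.25
  foreground quantile sits above the smoothed edge skirt for objects down
  to ~100 px diameter, so the refined cut lands at the half-height of the
  edge ramp — the point whose location is unbiased under symmetric
  smoothing — rather than at the foot of the skirt.

`assignWells()` maps each component centroid to the nearest well center of
a `DeviceLayout`, keeps the largest component per well (one spheroid per
well by design), and reports empty and multiply-occupied wells.

# Statistics

`mannWhitney()` is a two-tailed unpaired Mann–Whitney U test. The U
statistic is computed from midranks as the smaller of the two directional
statistics. The p-value is exact (full null distribution) when the pooled
sample has at most 16 observations with no ties, otherwise a normal
approximation with tie and continuity corrections is used; the path taken
is recorded. Fully tied data yield $p = 1$. Group summaries are mean ± SEM
(`summarizeValues()`), and `doseResponseTable()` assembles the standard
design: each treated dose versus its cell type's untreated control, plus
cell type versus cell type at matched doses, within timepoints.

# The synthetic scene generator

Real screening images from this class of experiment are typically not
shareable, so validation uses `generateScene()`: a parametric emulator with
exact per-spheroid ground truth.

## Geometry and channels

Each spheroid is a disk with a 1-pixel anti-aliased soft edge, placed at a
well center of the supplied layout. Per-spheroid diameters are drawn as
$\mathcal{N}(\mu \cdot \ell, \sigma^2)$ where $\mu$ is
`trueDiameterMean`, $\ell \geq 1$ is `looseningFactor` (treated spheroids
of some cell types loosen and spread), and $\sigma$ is `trueDiameterSd`;
with $\sigma = 0$ every diameter equals $\mu\ell$ exactly. Bright-field
renders dark disks (80) on a bright background (200); Hoechst bright disks
on a near-black background.

## Calcein radial profile

The calcein channel is designed so that true BAF is analytic. With viable
radius $R_v = R(1 - \text{deadRimFraction})$ and knee parameter
$k \in (0, 1]$, the radial profile is flat at `coreIntensity` to
$\tfrac{k}{2}R_v$, then falls linearly so that it crosses the 100 RFU
threshold *exactly* at $kR_v$, continuing down to a floor of 60 RFU held to
the spheroid edge. Hence the above-threshold disk has radius $kR_v$ and

$$\mathrm{BAF}_{true} = k^2, \qquad
  \mathrm{IMVIS}_{true} = \frac{\pi}{6}(2R_v)^3 \, k^2.$$

The floor keeps the full ROI detectable by segmentation while never
inflating the binary area. Defaults: $k = \sqrt{0.85}$ (BAF 0.85),
core 250 RFU.

Noise is Poisson (scaled by `poissonScale` photons/RFU) plus Gaussian read
noise, then rounded to integers in [0, 250]. All randomness derives from
the preset seed; reruns are bit-identical.

## Dose-response presets

`dxrPreset(cellType, dose)` returns calibrated presets for two sarcoma cell
types ("OS", "CS") at doxorubicin doses 0–10 µM (linear interpolation
between calibrated doses, saturating above 10). The two types are
calibrated to *different* response modes with the *same* index outcome at
10 µM — a 75% IMVIS drop:

* **OS**: viability retreats to a bright center — a dead rim grows
  (calcein area shrinks) while the remaining core stays bright
  (BAF-within-ROI stays at 0.85) and the bright-field outline loosens
  slightly ($\ell = 1.10$).
* **CS**: the outline loosens and the signal dims — no dead rim, but the
  core intensity drops toward the threshold and the within-ROI BAF falls.

Untreated diameter means are 327 µm (CS) and 285 µm (OS) with a 10 µm
between-spheroid SD.

## What the generator does and does not emulate

Emulated: well-plate geometry and per-well placement, disk-like spheroid
morphology with soft edges, radially decaying calcein signal, dead-rim
versus dimming dose responses, satellite debris (`satellites`), Poisson +
Gaussian sensor noise, integer quantization. Not emulated: non-circular or
lobed spheroids, intensity flat-fielding artifacts, focus drift, overlap
between neighboring spheroids, autofluorescence texture, or
spheroid-internal structure beyond the radial profile. Accuracy claims
validated on these scenes therefore bound rasterization, smoothing,
thresholding, and caliper error — not biological shape variation.

# Numerical choices

* **Pixel size** defaults to 1.4 µm/px; all physical outputs scale linearly
  (diameters) or cubically (V, IMVIS) with it, and BAF is invariant.
* **Smoothing** uses a compiled separable kernel (radius $3\sigma$) rather
  than FFT convolution: image dimensions here are frequently awkward for
  FFT sizes, and the direct pass is faster and exact at edges via replicate
  clamping.
* **Thresholding** operates on the smoothed image only for mask
  construction; BAF is always computed on the raw pixel values.
* **Exact vs approximate Mann–Whitney** switches at pooled $n = 16$; the
  exact path is validated against full enumeration of group assignments for
  pools of up to 10 values in the test suite.
* Problem sizes used in validation: scenes of 3–20 spheroids at 1.4 µm/px
  (chambers up to ~4500 × 900 px), masks up to 64 × 64 px for the
  exhaustive Feret oracle, pooled samples up to 10 for the exact
  Mann–Whitney oracle.

# Limitations

* Segmentation is global-threshold-based; heavy vignetting or uneven
  illumination would require flat-field correction upstream.
* The sphere-volume step assumes approximately spherical spheroids; for
  strongly elongated objects $D_{mean}$ overstates the minor axis's
  contribution to volume.
* BAF uses a single global threshold; it does not model partial-volume
  pixels at the viability boundary.
* The generator's ground truth is exact for its own model; agreement on
  synthetic scenes is necessary but not sufficient evidence of accuracy on
  real microscopy.
* All validation numbers quoted in the README are recomputed by the test
  suite and `scripts/acceptance.R`; this vignette intentionally states
  none beyond the calibrated preset definitions.
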