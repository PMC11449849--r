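---
title: "Quantifying microvasculature in OCT angiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvasculature in OCT angiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaq)
```

This vignette is the package's account of its science: what each stage of
the pipeline assumes, why the tunable parameters default to what they do,
what the synthetic phantoms do and do not emulate, and where the numerics
required a decision that the literature leaves open.

## The measurement problem

OCTA infers blood flow from the temporal decorrelation of back-scattered
light across N repeated OCT frames per position. Static tissue returns a
(nearly) identical signal every repeat; moving red blood cells decorrelate
it. A typical intraoral acquisition here is Z × X × Y × N =
950 × 400 × 400 × 4 voxels over a 5.25 mm × 5.25 mm field of view, i.e.
13.125 µm per lateral pixel. The axial pixel size is not used by any
metric; the default of 7.5 µm mirrors the axial resolution of the class of
swept-source systems this pipeline targets.

The goal is four reproducible numbers per tissue layer — vessel area
density (VAD, %), vessel skeleton density (VSD, %), vessel diameter index
(VDI, µm), and a diameter-weighted tortuosity index (WTI, unitless) — that
replace subjective reading of angiograms.

## Clutter filtering (wED)

Within a window of `window_z` × `window_x` pixels (full Y extent), frames
are unfolded to a (voxels × N) matrix, each frame's spatial mean over the
window is removed, and the N × N inter-frame covariance is
eigen-decomposed. The leading `n_static` eigenvectors span what is common
to all frames — static tissue — and are projected out; the output voxel
value is the RMS amplitude of the residual. Two design points:

* **n_static = 1 by default.** With N = 4 samples the covariance has four
  eigenvalues estimated from four frames; removing more than one component
  eats into the blood signal faster than it removes clutter.
* **RMS rather than squared amplitude.** Squaring doubles the dynamic-range
  penalty of depth attenuation: on two-layer phantoms, the deep plexus
  falls below a global Otsu threshold of the projected energy (Dice against
  truth 0.77) but stays well above it in RMS units (Dice 0.93–0.98). RMS is
  a monotone transform of the residual energy, so nothing else changes.
* **Windows overlap at 50% stride and are blended with triangular
  weights.** Non-overlapping windows leave visible block seams in the
  variance structure, which downstream local thresholds would pick up as
  edges. With a window at least the volume size, wED degenerates exactly to
  global ED — that identity is tested.

Mean removal per frame makes the output invariant to a constant offset on
all frames. A per-voxel temporal variance (`method = "variance"`) is kept
as the honest baseline the filter must beat (it does, by CNR, on every
temporal phantom).

## Depth-of-interest selection

The depth profile is the mean intensity of each Z slice. Two landmarks are
detected on a 9-slice moving average (raw per-slice means are speckle-noisy
at this sample size; 9 slices is narrow enough not to displace a plexus
peak):

* **End depth** — the deepest slice whose smoothed intensity is still at or
  above the mean over all depths. Exact equality with the mean essentially
  never occurs on sampled data, so the criterion is the last at-or-above
  crossing.
* **Separation depth** — the global maximum of the smoothed profile,
  searched from the first slice exceeding 10% of the profile maximum (so a
  surface-reflection artifact in air cannot win) to the end depth, ties
  broken toward the shallower slice.

Depth ranges are half-open and 0-based: DOI 1 = [0, separation),
DOI 2 = [separation, end). The peak slice itself belongs to DOI 2; some
assignment had to be made, and the partition property (the union of the two
projections equals the projection to the end depth) is exact under this
convention. A consequence worth knowing: vessels centered exactly at the
peak contribute their upper half to DOI 1 and the rest to DOI 2, so a
single anatomical vessel can appear in both layers. This is inherent to
intensity-based splitting, which reduces rather than eliminates overlap;
anatomical (e.g. learned epithelium) segmentation is out of scope here.

## From projection to vessel mask

The binary angiography mask combines three classical ingredients, but not
by a plain AND:

1. a **global Otsu gate**, `intensity > 0.6 × otsu(img)`, proposes the
   full-caliber candidate mask. Otsu is computed on an explicit 256-bin
   histogram with the threshold at a bin cut (ties to the lower cut), so it
   can be checked exactly against exhaustive search;
2. **Hessian vesselness** (Frangi-type: eigenvalues of the scale-normalized
   Gaussian Hessian, β = 0.5, structure scale at half the per-scale
   maximum, scales {2, 4, 6, 8} px ≈ 25–105 µm vessels at 13.125 µm/px),
   binarized by an **adaptive local-mean threshold** (window 51 px, offset
   0.01), provides tubularity *seeds*;
3. candidate components carrying seeds on less than 10% of their area are
   discarded; then objects under 30 px are removed and holes up to 20 px
   filled.

The seeded-reconstruction rule exists because a thresholded vesselness map
alone systematically under-covers vessel caliber — the ridge response
decays toward tube edges, costing ~15% of the area of a 5-px-wide vessel no
matter how the threshold is tuned — while the intensity gate alone admits
any bright noise blob. Letting intensity define extent and vesselness
define credibility recovers noise-free phantom masks at Dice 1.000 and
keeps the noisy-phantom penalty below 0.02.

## Skeleton, segments, and chain length

Zhang–Suen thinning produces the medial skeleton; two post-passes make it
strictly usable:

* **redundant-pixel removal** — thinning leaves staircase corners (a pixel
  whose two chain neighbors are themselves adjacent); every non-endpoint
  pixel whose set neighbors form a single 8-connected component is removed
  sequentially. This is topology-preserving by construction and leaves no
  fully-set 2×2 block;
* **spur pruning** — endpoint branches shorter than 5 px that terminate at
  a junction are deleted; they are boundary-noise artifacts with
  meaningless chords.

Segments are the 8-connected chains left after deleting branch points
(pixels with ≥ 3 set neighbors, which belong to no segment, making the
pixel partition unambiguous). A closed loop has no endpoints and a zero
chord; it is cut at its topmost-leftmost pixel and traversed as one open
chain (flagged via a message).

**Chain length** is the one place the obvious definition is wrong: the
classical (1, √2) step sum overestimates the length of digitally sampled
curves by ~5.5% on average (up to 8% at unfavorable orientations), which
the tortuosity index amplifies roughly threefold — a rasterized semicircle
would read TI ≈ 66 against the analytic 57.1. Segment length is therefore
the polyline length of the coordinate-smoothed chain (moving average of the
pixel coordinates, window 5, endpoints pinned). On axis-aligned and
diagonal chains the smoothed polyline is the original line, so the step
metric is reproduced exactly (a 3-step diagonal chain still measures 3√2);
on curved chains the zigzag bias is removed (semicircle within 1%).

**Diameters** follow the distance-transform definition: at each skeleton
pixel, twice the Euclidean distance to the nearest background pixel, zero
elsewhere; VDI is the skeleton mean of that field times the lateral pixel
size — an identity that is tested exactly, not approximately.

## Statistics

* Scan–rescan repeatability uses the **coefficient of variation with the
  population SD** (divisor n). Fed with published scan-pair values this
  convention reproduces six of eight published CVs exactly at four
  decimals; the two tortuosity cells of that reference follow the sample-SD
  convention instead (one of them inexactly), so one uniform convention was
  chosen and documented rather than mixing two.
* Cohort intervals are **Student-t**: mean ± t(0.975, n−1)·SD/√n. Against a
  published reference of 64 interval bounds recomputed from printed
  (mean, SD, n), 62 agree within one unit of the last printed digit — the
  attainable precision given that the printed inputs are themselves rounded
  — and the two bounds of one cell (floor of mouth, deep layer, WTI)
  disagree by 0.07 because that cell is internally inconsistent in the
  source (its interval implies SD 2.18 where 2.07 is printed).
* Heatmaps use an odd moving kernel (default 51 px ≈ 0.67 mm): plain window
  mean for density; for diameter and tortuosity the mean over skeleton
  pixels only, since background zeros would dilute the local statistic.

Reports print percentages, VDI and WTI to 2 decimals and CVs to 4, matching
the conventions of the reference tables; stored values keep full precision.

## The phantom: what it emulates, and what it does not

`make_structural_phantom()` builds a two-layer tubular network with
analytic ground truth:

* two coplanar plexuses at 0.25 Z and 0.55 Z; per-phantom tube radius drawn
  from 2–6 px; 8–15 sinusoidal vessels per layer, each in its own lateral
  lane so same-layer vessels never cross and every vessel is one
  branch-free segment with closed-form (quadrature) length and chord;
* per-vessel tortuosity targets drawn from 5–60, then amplitude/wavelength
  clamped to the lane width and to a bend radius of at least twice the tube
  radius (a tube that overlaps itself has no recoverable centerline);
  ground truth always records the TI of the final curve, not the target;
* the deep layer is never denser than the superficial one and backscatters
  at 0.85 relative amplitude on top of exponential attenuation
  (0.004 px⁻¹). Healthy-mucosa reference tables consistently show lower
  skeleton density in the deep layer, and the automatic separation *assumes*
  the superficial plexus hosts the global intensity peak — a phantom
  violating that assumption tests nothing about the method;
* speckle is multiplicative unit-mean Rayleigh (scale 1 by default) with
  additive Gaussian read noise (SD 0.05 of the unit vessel amplitude),
  standard intensity statistics for coherent imaging;
* the temporal phantom adds a static tissue field (identical across frames)
  and gives vessel voxels an AR(1) fluctuation with frame-to-frame
  correlation ρ (default 0: fully decorrelated flow); ρ = 1 with no noise
  is bitwise static and must reconstruct to zero.

Tubes are rasterized by pixel-center coverage (center within radius − ½ px
of the sampled centerline). The half-pixel allowance makes the
distance-transform diameter of a rasterized tube equal 2r — the convention
under which a radius-3 tube at 13.125 µm/px yields VDI 78.75 µm exactly —
at the cost of a slight (≤ 1/(2r)) area deficit, the direction chosen
because the diameter enters two metrics and the area only one.

**Recovery protocol.** The separation depth is scored against the
superficial layer's center through `split_doi()`. The area/diameter/
tortuosity metrics are scored on the projection from the surface to the
midpoint between the *detected* separation and end depths: the half-open
split assigns the peak slice to the deep layer, so the superficial DOI
alone would truncate the brightest slice of a perfectly thin plexus — an
artifact of phantom coplanarity, not of the method. The midpoint bound uses
detected quantities only and covers the full superficial plexus and none of
the deep one. Across ten seeded noise-free phantoms the recovery errors are
VAD 0.0 points, VDI ≤ 0.4 px, WTI ≤ 0.3, separation ≤ 2 slices
(`scripts/acceptance.R` recomputes these).

What the phantom does **not** emulate: real optical PSFs and shadowing
below large vessels, bulk-motion artifacts, capillaries above the
superficial plexus, anatomically curved layer boundaries, and flow-speed-
dependent decorrelation. Passing the phantom suite therefore demonstrates
correctness of the geometry and statistics, not clinical-grade robustness.

## Problem sizes and numerical conventions

The validation suites run phantoms at the generator default of
256 × 256 × 256 (structural) and 96 × 96 × 96 × 4 (temporal); one
structural phantom plus full quantification takes a few seconds on one
CPU. Volumes are stored as raw float64 with a JSON sidecar (exact round
trip) or multi-page float32 TIFF with a recorded linear rescale; en face
images as 8/16-bit PNG/TIFF with the rescale in a sidecar; masks as 0/255
PNG. All depth indices in reports are 0-based half-open; all R-facing slice
arguments are 1-based inclusive, the package's containers documenting
which. Degenerate inputs have defined behavior: constant images refuse an
Otsu threshold, all-zero acquisitions reconstruct to zero with a warning,
an empty skeleton refuses VDI, a background-free mask falls back to
image-border distances with a warning, and a constant en face image is
written as zeros with a warning.

## Known limitations

* Separation at the *global* peak means a dominant deep plexus would be
  labeled superficial; the phantom enforces the intended ordering, real
  tissue with inverted contrast would need manual review.
* The tortuosity of segments shorter than ~10 px is dominated by
  discretization even after chain smoothing; segments under 5 px are
  discarded outright.
* WTI weights segments by their mean diameter, so mask caliber errors move
  WTI twice (through the weight and through segment selection).
* The wED variant here is a standard eigen-decomposition clutter filter;
  vendor implementations differ in window geometry and regularization, so
  absolute intensities are not comparable across implementations — the
  derived binary masks and metrics are.
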