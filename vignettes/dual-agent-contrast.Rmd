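---
title: "Quantifying dual-agent fluorescence contrast in 3D brain volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual-agent fluorescence contrast in 3D brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocontrast)
```

## The problem

Fluorescence-guided surgery (FGS) agents such as ALA-induced
protoporphyrin IX (PpIX) and second-window indocyanine green (ICG) both
produce strong bulk tumor contrast in gliomas, but they accumulate in
very different parts of the tumor: PpIX-type contrast tends to be
brightest near the tumor rim, while retained ICG is brightest in the
tumor core. Block-face cryo-imaging of a whole brain yields
intrinsically co-registered 3D volumes of both agents at high
resolution, which makes it possible to ask quantitative questions that
2D sections cannot answer: how does each agent's signal vary with
distance from the tumor boundary, how much contrast is left exactly at
the resection margin, and how correlated are the two distributions?

`cryocontrast` implements that analysis as a reusable package: volume
and mask I/O, distance-resolved shell decomposition, whole-tumor and
margin contrast metrics, joint histograms, region-restricted
correlation, and a synthetic phantom generator that reproduces the
statistical structure the analysis assumes, so every estimator can be
validated against exact ground truth.

## Regions and the distance transform

All regions derive from one geometric primitive, the Euclidean distance
to the tumor boundary, computed in physical millimetres with per-axis
voxel spacing (`boundary_distance()`, a separable lower-envelope
distance transform in compiled code). The convention is voxel-center to
voxel-center: a tumor voxel face-adjacent to background has
`d_in = spacing`, so on a 1 mm isotropic grid the band
`0 < d_in <= 1` is exactly the layer removed by one binary erosion.

From the distance field the package builds:

* **inward shells** (`inward_shells()`): shell *k* is
  `(k-1)t < d_in <= kt` at pitch `t` (default 1 mm). The shells are
  pairwise disjoint and their union is exactly the tumor mask;
  construction stops at the first empty shell.
* **outward shells** (`outward_shells()`): the same banding on `d_out`,
  intersected with a brain mask so peritumoral shells stay in tissue.
* **margin regions** (`margin_regions()`): the first inward and first
  outward shell — the outer 1 mm of tumor and the adjacent 1 mm rind.
* **boundary band** (`boundary_band()`): all voxels within a half-width
  (default 1 mm, i.e. a 2 mm thick band) of the surface on either side.
* **contralateral reference** (`contralateral_region()`): a voxel-exact
  mirror of the tumor mask across an axis-aligned symmetry plane,
  rejected if it leaves the grid or touches the tumor.

Distance banding was chosen over literal iterated erosion because
erosion is ambiguous for anisotropic voxels, while a band in mm is well
defined on any grid. The two agree where the comparison is meaningful:
the first shell equals one unit-ball erosion on any isotropic mask, and
all shells match iterated erosion on convex masks (the test suite pins
the 7×7×7 cube, whose shells count 218/98/26/1 voxels). They can
diverge in deep shells of strongly concave masks, where repeated
digital erosion effectively measures a city-block distance; the
Euclidean banding is taken as the definition.

## Contrast metrics

With population statistics (`sd` divides by *n*; a mask is an
exhaustive voxel set, not a sample) over a region `R`:

* **TBR (whole)** = mean(tumor) / mean(contralateral reference);
* **TBR (margin)** = mean(outer 1 mm of tumor) / mean(1 mm peritumoral
  rind);
* **CNR** = (mean(signal) − mean(reference)) / sd(reference), with the
  contralateral region as reference for the whole-tumor variant and the
  peritumoral rind for the margin variant;
* **CC** = Pearson correlation of the paired voxel intensities of the
  two channels within a region (bulk tumor, and the 2 mm boundary
  band). CC is invariant under positive affine rescaling of either
  channel, so raw and normalized intensities give the same value.
* **shell profile** (`shell_profile()`): mean intensity per shell,
  normalized to the brightest shell, plotted against signed
  mid-distance ((k−0.5)t, negative inward);
* **line profile** (`line_profile()`): trilinear interpolation along a
  physical segment, normalized to its maximum. Samples are restricted
  to the span of voxel centers so interpolation never extrapolates.
* **joint histogram** (`joint_histogram()`): both channels are min-max
  normalized to [0, 1] *within the analysis region* and counted on a
  100×100 uniform grid; the last bin is right-closed so the maximum is
  counted and total counts equal the region size.
  `slice_histogram()` extracts the frequency of one channel's values
  for a fixed normalized band of the other (e.g. 0.40–0.42).

Degenerate inputs are hard errors rather than silent NA: an empty mask,
a non-positive reference mean (TBR), or a constant region (CNR
denominator, CC, min-max normalization) each abort with a message
naming the quantity that is undefined.

## The synthetic phantom

`phantom_spec()` describes a brain-shaped ellipsoid containing an
ellipsoidal tumor and capsule-shaped ventricles; `generate_phantom()`
evaluates a noiseless intensity model driven by the tumor boundary
distance, multiplies ventricle voxels by a per-channel gain, adds
independent Gaussian noise and clips at zero. Identical spec and seed
give bit-identical volumes.

With background `b`, peak amplitude `p`, and boundary distance `d`:

* **channel A (rim-enhancing, PpIX-like)**, inside the tumor:
  `b + p·(f + (1−f)·exp(−d/w))` with center fraction `f = 0.125` —
  the rim is eight times brighter than the deep core, the one
  quantitative anchor the model exposes — and rim width `w` (default
  1.5 mm). Outside, the boundary value `b + p` decays as
  `exp(−d/λ)` with peritumoral length `λ` (default 2 mm).
* **channel B (core-enhancing, ICG-like)**, inside:
  `b + p·(1 − exp(−d/ℓ))`, rising monotonically with depth (rise
  length `ℓ`, default 3 mm). Outside, the value of the boundary voxel
  layer decays with the same peritumoral length. The boundary value is
  the inside model at depth `d₀ = min(spacing)`: under the
  voxel-center convention the shallowest tumor voxels sit at
  `d ≈ spacing`, so this makes the discrete field continuous across
  the boundary layer. (The continuum limit of the inside model at
  `d = 0` is exactly `b`, which would leave the core agent with no
  peritumoral halo at all — contradicting the elevated peritumoral
  signal both agents show — hence the voxel-layer convention.)

Exponential kernels are a modeling choice: the underlying radial laws
in real tumors are unknown, and only the qualitative shapes (rim peak,
core peak, decaying halo) plus the ~8× rim-to-center ratio are treated
as anchored. Noise is additive Gaussian only — the analysis needs a
controllable reference-region standard deviation, not a physically
faithful shot-noise model — and clipping at zero reflects non-negative
fluorescence. Ellipsoid/capsule geometry rather than an anatomical
atlas keeps masks analytic, so tests can do exact region bookkeeping.

`analytic_region_means()` evaluates the same noiseless model over the
canonical regions (tumor, both 1 mm margins, mirrored contralateral) by
direct evaluation, giving exact ground truth for parameter-recovery
tests; the test suite independently re-derives it with all-pairs
brute-force distances and explicit model loops.

### Default study conditions

The generator's defaults describe one fixed condition set: a 64³ grid
at 1 mm isotropic spacing, a ~26 mm brain ellipsoid containing a
~7–8 mm-semiaxis tumor offset into one hemisphere, two 1.5 mm-radius
ventricle capsules near the midline (gain 1.6 in A, 3 in B — ventricle
enhancement is more pronounced in the ICG-like channel), backgrounds
250/150, peaks 5000/6000, and noise sd 20 per channel. These give
whole-tumor TBRs of order 10–20 and strongly negative bulk-tumor CC,
the regime the analysis is designed for; none of the resulting metric
magnitudes are asserted by tests, only the structural pattern (rim
profile peaks in the outermost shell, core profile in the innermost,
margin TBR well below whole-tumor TBR, negative bulk CC).

### Two numerical facts worth knowing

*Isotropic noiseless degeneracy.* On an isotropic grid every voxel of
the first outward shell has `d_out` exactly equal to the spacing, so a
noiseless, purely distance-driven phantom is *constant* there and the
margin CNR is genuinely undefined — the package raises the constant-
region error rather than returning an arbitrary number. Real data (or
any nonzero noise, or anisotropic spacing) breaks the degeneracy; the
pipeline's noiseless example test uses anisotropic spacing for this
reason.

*Clipping floor for CNR studies.* Noise is clipped at zero, so CNR
calibrations should keep the implied noise sd well below the background
level. The stochastic recovery test targets an analytic whole-tumor
CNR of 10 on a background-500 phantom with moderate peaks (rim 1000,
core 1200) and a 1 mm peritumoral decay, which puts the implied sd
(~39) more than ten standard deviations above the clipping floor and
keeps the mirrored reference region flat, so the measured reference sd
estimates the noise sd alone.

## Pipeline and reproducibility

`analysis_config()` + `run_analysis()` orchestrate the whole analysis
from a YAML-serializable config with exactly one input source (file
paths or a phantom spec). Outputs are `report.json` (all metrics and
region statistics, byte-identical across runs at a fixed seed),
per-channel shell-profile CSVs, joint-histogram CSV matrices with JSON
sidecars (bin edges and normalization parameters), multi-label shell
volumes for visual inspection, and `run.log` with the voxel count of
every region — the auditable intermediate behind every metric — plus
input hashes. Failures name the stage and remove partial outputs.
`cryo_cli()` exposes `generate-phantom`, `analyze` and `shells`
subcommands with conventional exit codes.

## Test problem sizes

The suite validates estimators against independent brute-force oracles
at sizes chosen so exact all-pairs computations stay cheap: distance
transforms on grids up to 14³ (all-pairs oracle), analytic-mean
recovery on a 40³ grid with an 8 mm spherical tumor, noiseless
end-to-end recovery on the default 64³ phantom at 1e-10 relative
tolerance, and stochastic CNR recovery over 20 seeds on 32³ phantoms.

## Limitations

The phantom does not simulate excitation/emission spectra, optical
attenuation with depth, scanner PSF, or anatomical tissue texture; its
normal brain is spatially flat apart from ventricles and the
peritumoral halo. Passing recovery tests therefore demonstrates that
the estimators measure what they claim on data obeying the stated
model — not that the model captures every feature of real cryo-imaging
volumes. Masks are taken as given (no segmentation is performed), no
resampling is ever done (mismatched grids are a hard error), and the
contralateral reference requires an explicit symmetry plane rather than
automatic mid-sagittal detection.
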