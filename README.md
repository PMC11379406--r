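# cryocontrast

Quantitative comparison of two fluorescence-guided-surgery (FGS) agents
in co-registered 3D brain volumes. Block-face cryo-imaging of a whole
brain produces intrinsically registered intensity volumes for each
agent — typically an ALA-PpIX-like channel that is brightest near the
tumor rim and a second-window-ICG-like channel that is brightest in the
tumor core. `cryocontrast` computes every standard contrast comparison
between such channels and ships a synthetic phantom generator with
analytic ground truth so the whole measurement chain can be validated.

Given a tumor mask *T*, a normal-tissue reference *N* (a voxel-exact
mirror of *T* across a symmetry plane), and per-voxel intensities, the
package computes, per channel:

- **TBR (whole)** = mean(T) / mean(N), and **TBR (margin)** =
  mean(outer 1 mm of T) / mean(adjacent 1 mm peritumoral rind);
- **CNR** = (mean(signal) − mean(reference)) / sd(reference), with
  population sd, for the same two region pairs;
- **shell profiles**: mean intensity in concentric shells of fixed mm
  pitch inward and outward from the tumor boundary (Euclidean distance
  transform in physical mm, anisotropic voxels supported), normalized
  to the brightest shell;
- **line profiles** by trilinear interpolation;

and, between the two channels:

- **CC**: Pearson correlation of paired voxel intensities over the bulk
  tumor and over a 2 mm band spanning the tumor boundary;
- **joint histograms**: 100×100 counts of region-wise min-max-normalized
  intensities, with marginal and band-slice extraction.

Volumes and masks are read and written as NRRD, NIfTI-1 (`.nii`,
`.nii.gz`) or numbered TIFF stacks with a YAML spacing sidecar; arrays
are `(z, y, x)` with spacing in mm per axis, and mismatched grids are a
hard error (no resampling is ever performed).

## Worked example

```r
library(cryocontrast)

spec <- phantom_spec(seed = 1L)      # 64^3 brain phantom, 1 mm voxels
ph <- generate_phantom(spec)
ph$channel_A
#> <volume3d> 64 x 64 x 64 (z,y,x), spacing 1 x 1 x 1 mm, range [0, 3347.42]
ph$tumor
#> <label_mask 'tumor'> 64 x 64 x 64 (z,y,x), spacing 1 x 1 x 1 mm, 1648 voxels set

rep <- run_analysis(analysis_config(phantom = spec, output_dir = "demo_out"))
str(rep$channels)
#> List of 2
#>  $ A:List of 4
#>   ..$ tbr_whole : num 8.73
#>   ..$ tbr_margin: num 0.951
#>   ..$ cnr_whole : num 94.8
#>   ..$ cnr_margin: num -7.86
#>  $ B:List of 4
#>   ..$ tbr_whole : num 20
#>   ..$ tbr_margin: num 1.57
#>   ..$ cnr_whole : num 147
#>   ..$ cnr_margin: num 32.5
unlist(rep$cross_correlation)
#>      tumor       band
#> -0.9872944 -0.9680508
```

Both channels show high whole-tumor contrast (TBR 8.7 and 20, CNR 95
and 147), but the margin-restricted variants collapse (TBR ≈ 1–1.6):
at the resection margin the rim agent's peritumoral halo is nearly as
bright as the rim itself. The strongly negative bulk-tumor CC (−0.99)
reflects the complementary spatial distributions — one agent rises
toward the boundary exactly where the other falls.

The shell decomposition behind the distance-resolved profile:

```r
dec <- inward_shells(ph$tumor)       # 1 mm concentric shells
dec
#> <shell_decomposition> inward, 1 mm pitch, 7 shell(s): 504/432/352/160/144/48/8 voxels
round(shell_profile(ph$channel_A, dec, channel = "A")$values, 3)
#> [1] 0.299 0.318 0.357 0.425 0.540 0.766 1.000
```

The rim channel's profile rises monotonically from the 6–7 mm-deep
core (≈0.3, i.e. the ~8× rim-to-center ratio plus background) to the
outermost shell. `run_analysis()` also writes `report.json`, profile
CSVs, the 100×100 joint-histogram matrices with JSON sidecars,
multi-label shell volumes, and a log with every region's voxel count.

A command-line wrapper is provided at `inst/cli/cryocontrast`:

```sh
Rscript inst/cli/cryocontrast generate-phantom --seed 7 --out phantom/
Rscript inst/cli/cryocontrast analyze --config analysis.yaml
```

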