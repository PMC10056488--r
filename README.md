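# vessel3d

An R toolkit for quantitative coronary artery imaging: it segments
intravascular OCT pullbacks (lumen and adventitia borders, metallic and
bioresorbable stent struts), segments CT coronary angiography (CTCA)
volumes (lumen, outer wall, calcified and non-calcified plaque, stent
extent), fuses the per-frame 2D results onto a 3D centerline with lofted
surface meshes, and computes the vessel and stent metrics used in
interventional cardiology. It is aimed at imaging researchers who need an
offline, scriptable, fully reproducible counterpart to interactive
workstation tools.

Clinical pullbacks cannot be redistributed, so the package ships seedable
synthetic phantom generators (speckle-textured polar OCT frames; HU-valued
tubular CT volumes) with exact ground truth, and its entire validation
suite runs against those phantoms.

## Methods at a glance

* **OCT borders.** Guidewire artifact removal via the Harris–Stephens
  corner response plus a full-depth-shadow test; bilateral denoising; lumen
  border as a fast-marching minimal path on the speed
  `F = ε + (1 − ε) R`, where `R` is the intensity × positive-radial-gradient
  ridge of the intima transition; adventitia via an 11 × 11
  standard-deviation image followed by a Frangi vesselness filter tuned to
  the 31-px dark media ring.
* **Stent struts.** Per-scan-line bright-peak + shadow-length + slope
  criteria, clustered with DBSCAN (eps 0.15 mm) to one point per strut;
  BVS struts via threshold-0.15 binarization, closing, hole filling,
  subtraction, and area/aspect/lumen-band rules.
* **CTCA.** Multiscale Frangi vesselness; minimum-cost-path centerline
  (26-neighborhood, cost `1/(ε + vesselness)`); sigmoidal class weights
  calibrated from user seed voxels; 3D level-set evolution with speed
  `(2 w(I) − 1) − κ·curvature`; stent localization by a luminal-statistics
  adapted sigmoid over the perilumenal shell.
* **Fusion and metrics.** Rotation-minimizing frames along the centerline;
  rigid per-frame placement (an exact isometry); lofted triangle meshes
  sliced every 0.5 mm and compared with the 2D series via r², RSS and
  Bland–Altman limits `bias ± 1.96 sd`; plaque burden
  `100 (A_wall − A_lumen)/A_wall`, stent CSA, malapposition, restenosis
  burden, fracture flags.
* **Classifier bookkeeping.** Patch extraction in the lumen–adventitia ROI,
  rotation augmentation, frame-grouped 70–30 splits, and the 9-block CNN
  architecture specification — counts and shapes only, no clinical model.

The methods vignette (`vignettes/methods.Rmd`) documents every model,
parameter and design decision in detail.

## Worked example

Generate a 3-frame phantom pullback with a guidewire, segment both borders,
and compute per-frame vessel metrics:

```r
library(vessel3d)

spec <- oct_phantom_spec(n_frames = 3, guidewire_angle = 200, noise_seed = 7)
ph   <- synth_oct_pullback(spec)
segs <- segment_pullback(ph$frames)
vessel_metrics_pullback(segs, radial_spacing = 0.01)
#>   frame lumen_area_mm2 lumen_perimeter_mm wall_area_mm2 wall_perimeter_mm
#> 1     1          7.069              9.429         15.12             13.79
#> 2     2          7.068              9.425         15.12             13.79
#> 3     3          7.069              9.429         15.12             13.79
#>   plaque_burden_pct
#> 1             53.25
#> 2             53.27
#> 3             53.26
```

The phantom's lumen radius is 1.5 mm and its adventitia radius 2.2 mm, so
the analytic targets are a lumen area of π·1.5² = 7.069 mm², a wall area of
π·2.2² = 15.21 mm² and a plaque burden of 53.5% — the segmented values above
agree to better than 1%. Against the generator's ground truth the
first frame scores a lumen Dice of 0.9999 and a Hausdorff distance of
0.01 mm:

```r
radial_dice(segs[[1]]$lumen$radii, ph$truth$lumen_radii_px[1, ])
#> [1] 0.9999
radial_hausdorff(segs[[1]]$lumen$radii, ph$truth$lumen_radii_px[1, ], 0.01)
#> [1] 0.01
```

A command-line front end (`inst/cli/vessel3d`) wraps the same pipeline:
`vessel3d phantom-oct --out d --seed 7`, `vessel3d oct-segment --in d --out r`,
`vessel3d oct-struts …`, `vessel3d ctca-segment …`, `vessel3d fuse …`,
`vessel3d metrics …`, `vessel3d patches …`.

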