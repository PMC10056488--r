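---
title: "Methods: coronary OCT/CTCA segmentation and 3D reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coronary OCT/CTCA segmentation and 3D reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vessel3d reconstructs coronary artery anatomy from two imaging routes:
intravascular optical coherence tomography (OCT) pullbacks, analyzed frame by
frame in polar coordinates, and CT coronary angiography (CTCA) volumes,
segmented in 3D. A fusion stage lifts the per-frame 2D results onto a 3D
centerline and builds surface meshes, and a metrics stage derives the
quantities interventional cardiologists read off such reconstructions: lumen
and wall areas, plaque burden, stent cross-sectional area, strut
malapposition, restenosis, and fracture flags. Because clinical pullbacks
cannot be redistributed, every stage is validated against synthetic phantoms
with exact ground truth; this vignette documents the models, the parameters
that matter, and the design decisions taken where the method family leaves
choices open.

## Polar OCT conventions

A pullback is a stack of polar frames: row `i` is the A-line at angle
`theta = 2*pi*(i-1)/n_alines` (counter-clockwise, theta = 0 at the image
top), column `j` is depth in pixels from the catheter center, and intensities
are normalized to [0, 1]. All file interfaces use 0-based indices, half-open
intervals and millimeters; contour polygons are counter-clockwise with the
first vertex not repeated.

## Guidewire artifact removal

The guidewire occludes a contiguous angular sector, leaving a bright
reflection near the catheter and a shadow through the full imaging depth.
The detector computes the Harris–Stephens corner response on the frame,
marks A-lines whose far-field (deepest 30%) mean intensity falls below 40%
of the across-frame median, groups them into periodically contiguous runs,
and flags the run with the strongest total corner response that also carries
a strong corner (above the 0.9 quantile of per-line maxima). The flagged
sector, widened by two A-lines of penumbra, is masked: border radii there
are interpolated periodically and never measured. Exactly one run is masked
per frame — the wire is a single physical object — which also prevents strut
shadows from being misread as wire on stented frames.

## Lumen segmentation by fast marching

The lumen border is the dark-to-bright intima transition. The frame is first
denoised with an edge-preserving bilateral filter (spatial sigma 5 px, range
sigma 0.1; both configurable). The method family prescribes a fast-marching
minimal path but leaves the speed function open; we use

    F = eps + (1 - eps) * R,   eps = 0.01,

where `R` is the ridge response: the Gaussian-smoothed image (sigma 2 px)
times its positive radial gradient, rescaled to [0, 1]. `R` peaks at the
intima step; `eps` keeps arrival times finite in featureless regions. The
eikonal equation `|grad T| = 1/F` is solved by a first-order fast-marching
scheme from a seed on the first A-line (the ridge argmax after smoothing
across neighboring A-lines, which tracks eccentric lumens), and the path is
extracted by steepest descent on `T` from the far side. Closure is enforced
by duplicating the first eight A-line rows below the image and accepting the
traversal whose end column lies within 3 px of the seed column. Masked
A-lines are interpolated periodically, and the radii get a circular 5-tap
median, which suppresses single-pixel path quantization. Re-runs are
bit-identical; there is no randomness anywhere in the pipeline.

## Adventitia segmentation

The outer (adventitia) border shows as the end of a dark media ring between
bright tissue and residual background signal. The pipeline is: bilateral
filter, an 11 x 11 neighborhood standard-deviation image, then a single-scale
Frangi vesselness filter with dark-ridge polarity tuned to a ring thickness
of 31 px (`sigma = 31 / (2 sqrt 3)`, the scale at which a bar of that width
maximizes the normalized second derivative). In the standard-deviation image
the media is a low-variance valley flanked by high-variance transitions, a
tubular continuous structure the vesselness filter enhances. Per A-line we
take the *outermost* contiguous run of responses above threshold 0.05 —
low-variance bands inside the tissue can also respond, but the media ring is
by construction the outermost — and place the border at the run's response
peak plus half the tuned thickness (the filter localizes the ring center;
the border is its outer edge). A-lines with no qualifying response are
interpolated; if more than half fail, the frame is rejected as "adventitia
not recoverable".

## Metallic and bioresorbable strut detection

Metal struts bloom and cast full-depth shadows. Per scan line, the brightest
pixels above the 99.5th per-line intensity percentile are retained; the line
is a candidate iff the profile drops behind the peak with slope at least
0.08 intensity/px within 5 px, and the mean intensity over the 60 px
starting 10 px behind the peak stays below the shadow level. The shadow
level is 20% of the median intensity of the 50-px band beyond the lumen
border — the tissue an unshadowed beam would illuminate. (A frame-global
percentile and a whole-depth median were tried first and discarded: the
former drops speckle-dimmed blooms, the latter is dominated by dark far
field and accepts everything.) Candidates are clustered with DBSCAN
(eps 0.15 mm, min_pts 1; deployed struts sit >= 0.6 mm apart) and each
cluster is reduced to its intensity-weighted centroid. DBSCAN runs per
frame; struts are linked across frames later, in the fusion stage (0.3 mm
gating between adjacent frames).

BVS struts are bright-rimmed dark boxes at the lumen border, detected on the
scan-converted cartesian frame by the fixed rule chain: min-max normalize,
binarize at 0.15, morphological closing with a one-pixel-radius disk, fill
holes, subtract the binarized image; 8-connected components of the
difference survive iff their area is within [10, 40] px, their
second-moments ellipse aspect ratio is below 5, and their centroid lies
within the 10-px band centered on the lumen border.

## CTCA segmentation

Volumes are preprocessed with multiscale Frangi vesselness (bright-tube
polarity, scales 1/1.5/2 mm, maximum over scales; the Hessian-based
normalization makes the response invariant to global HU offsets). The
centerline is the minimum-cost path between two user seeds over the
26-neighborhood with per-voxel cost `1/(0.05 + vesselness)` and metric edge
lengths, smoothed by a 5-point moving average.

Class membership is expressed by sigmoidal weight functions calibrated from
user seed voxels. The lumen weight is a band (product of a rising and a
falling sigmoid) with midpoints at the 5th/95th percentiles of the
lumen-seed HU (widened to 10 HU when degenerate) and slope `4/max(IQR, 5)`.
The wall weight is also a band: the falling sigmoid sits midway between the
wall-seed mean and the lumen-seed 5th percentile; a rising cut
`max(4 IQR_wall, 20)` HU below the wall mean bounds the class against low-HU
background and non-calcified plaque — with a falling sigmoid alone,
everything below the wall HU (including air and fat) would be wall-typical
and the outer-wall front would grow without bound. The calcified-plaque (CP)
weight is a rising sigmoid midway between the lumen-seed 95th percentile and
the CP-seed mean. Calibration refuses seed sets whose means are not ordered
wall < lumen < CP.

Segmentation is a 3D level set (narrow-band, first-order upwind, curvature
clamped at grid scale): the lumen front starts as a 1-voxel tube around the
centerline and evolves with outward speed `(2 w_lumen(I) - 1)` minus 0.2
times mean curvature, time step 0.4, at most 500 iterations, declared
converged when the labeled volume changes by less than 1e-3 (relative) over
10 iterations; the outer wall runs the same scheme seeded from the lumen
result with the wall weight, restricted to a 5 mm radius around the
centerline (a generous bound on coronary wall extent). CP voxels are the
connected components of `w_cp > 0.5` outside the lumen that touch the wall
region — calcium repels the wall front itself, so literal containment never
holds. Non-calcified plaque has no weight function of its own; it is defined
by exclusion: between lumen and outer wall, not CP, and not wall-typical
(`w_wall <= 0.5`). Labels compose with precedence
stent > CP > lumen > NCP > wall.

Stent detection scores perilumenal shell voxels (the morphological gradient
of the lumen mask, dilated by one voxel) with a rising sigmoid whose
midpoint adapts to the luminal intensity (`mean + 3 sd`); per 0.5 mm
centerline station the score is the fraction of shell voxels above weight
0.5, and the stent extent is the longest contiguous run of stations scoring
above 0.1. Because the midpoint tracks the luminal statistics, rescaling the
stent contrast leaves the extent unchanged.

## Fusion and meshing

Frames are placed along the centerline with rotation-minimizing (parallel
transport) frames rather than Frenet frames, which are undefined on straight
segments and flip at inflections. The centerline is resampled at 0.5 mm;
tangents come from central differences; each normal is the previous one
projected orthogonal to the new tangent. Frame `i` maps to arclength
`offset + i * frame_spacing`, refined through a linear landmark fit when at
least two landmarks (arclength, frame) are supplied — the frame count
exceeds the model's cross-section count, so registration cannot be
point-to-point. Each 2D point maps rigidly to
`C(s) + x n(s) + y b(s)`; in-frame distances and areas are preserved
exactly, which the tests assert to 1e-9. The absolute rotation of the frames
about the centerline is unrecoverable without angiographic cues; a fixed
initial normal is used, which affects strut azimuth but no area or diameter.

Rings are lofted into a triangle mesh (quads split in two, seam aligned by
minimal cyclic twist, flat centroid-fan caps, outward orientation enforced
via the signed volume); optional Laplacian smoothing (lambda 0.1, 5
iterations) is off by default and shrinks cross-sections by under 1%.
Model-versus-frames comparison slices the mesh every 0.5 mm with planes
orthogonal to the centerline, computes areas and area-equivalent diameters
`2 sqrt(A/pi)` ("diameter" is not otherwise defined for non-circular
sections), and reports r², residual sum of squares, and Bland–Altman bias
with 1.96-sd limits of agreement.

## Metrics

Polygon metrics use the shoelace area, polyline perimeter, maximum pairwise
vertex distance, and rotating-calipers minimum width. Plaque burden is the
standard EEM-based `100 (A_wall - A_lumen)/A_wall`. Stent cross-sectional
area is the area of the strut polygon ordered by azimuth about the lumen
centroid (stent-model fitting is out of scope). Malapposition is the radial
distance from the strut's abluminal edge (center plus strut thickness,
default 0.1 mm) to the lumen contour, positive toward the lumen cavity; a
strut is unapposed above 0.1 mm. Restenosis burden is
`100 (CSA - A_lumen)/CSA` clipped at zero. Fracture is flagged for any run
of at least 3 consecutive strut-free frames strictly inside the stented
extent — a concrete reading of "fracture detection" as a frame-gap
heuristic.

## Patch bookkeeping and classifier architecture

The plaque-classification data preparation is reproduced as pure
bookkeeping: patch centers are drawn uniformly (seeded) from the pixels
between the lumen and adventitia contours (1000 per frame, 25 x 25 px
patches clipped to the frame); augmentation adds one copy per rotation in
{90°, 180°}, never rotating a rotation; the 70–30 split partitions frames,
not patches, so no frame leaks between training and validation. With 300
frames this yields 300,000 originals, 900,000 augmented samples, and a
630,000/270,000 split. The architecture specification chains nine 3 x 3
convolution blocks (batch norm + ReLU; filters 32/32/32/64/64/64/128/128/128
for OCT and 16/16/16/32/32/32/128/128/128 for the lower-resolution IVUS
variant), max pooling after blocks 3 and 6, global average pooling, a
512-neuron fully connected layer, dropout 0.5, and a final fully connected
layer sized to the class count. The class count defaults to 5 (four plaque
types plus background); a 3-neuron final layer would be inconsistent with
five predicted classes. The OCT patch size is not fixed by the method
description; it defaults to the IVUS value of 25 px. No clinical model is
trained or shipped: the published plaque accuracies depend on expert-annotated
frames that are not available.

## Synthetic phantoms: what they do and do not show

The OCT phantom renders, per A-line, a dark lumen, a bright intima step
exactly at the true lumen radius with an exponential decay into a tissue
band, a dark media ring ending exactly at the true adventitia radius, and a
decaying background; a guidewire sector (bright reflection, 2% transmission
shadow), metal struts (Gaussian blooms with shadows attenuated to 5% of the
template) and BVS boxes are stamped on top, then everything is multiplied by
exponential speckle with a 1.5 px grain (a smoothed unit-mean exponential
field). The CT phantom rasterizes a parametric tube (line or helix) with
flat ends into the six tissue classes at plausible HU (background -100,
NCP 20, wall 50, lumen 350, CP 800, stent 1100), then optionally blurs and
adds Gaussian noise. Both generators are bit-reproducible from their
mandatory seed, and truth shares the image grid conventions.

The validation suite runs at fixed sizes — 50 border frames, 20 strut frames
with 8 struts each, a 64 x 64 x 110 voxel tube at 0.4 mm, a 20-frame fusion
pullback — chosen to exercise every code path at interactive runtimes.
Passing it shows the algorithms recover known geometry under speckle and
noise of realistic texture; it does not show clinical-grade accuracy: the
phantoms have no eccentric wall composition, no blood artifacts, no motion,
no bifurcations, and their appearance model is the same family of cues the
detectors key on. The published clinical figures for these methods were
measured on data that is not redistributable and are therefore out of reach
of this package's tests by construction.

## Numerical choices and degenerate inputs

Fast marching uses the standard two-axis upwind quadratic update with a
binary heap; path descent is discrete 8-neighbor steepest descent. The level
set clamps phi to ±3 voxels (narrow band) and the curvature term to grid
scale. Gaussian smoothing truncates kernels at 3 sigma with reflective
boundaries. Blank frames raise "no lumen detected"; all-bright frames raise
"adventitia not recoverable"; zero-length centerlines, struts outside the
imaged depth, unordered HU seeds, inconsistent intensity orderings and
self-intersecting polygons are rejected with explicit errors. Ties in the
seam-closure search resolve to the lowest arrival time; DBSCAN labels are
stable under input permutation up to relabeling, which the tests assert.

## Known limitations

Catheter offset is assumed zero in the phantoms; IVUS segmentation is not
reimplemented (externally supplied contours flow through metrics and fusion
unchanged); the two-view angiographic reconstruction that would supply a
clinical centerline is an input, not a module; wall segmentation quality in
CTCA depends on the seed annotations bounding the wall HU band; and the
frame-gap fracture heuristic cannot distinguish a true fracture from a run
of detection failures.
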