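---
title: "Stereo recognition of transplanted seedlings: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereo recognition of transplanted seedlings: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the science behind `seedling3d`: the models in
each pipeline stage, the parameters that matter and why their defaults
are what they are, what the synthetic scene generator does and does
not emulate, and the numerical choices and limitations a user should
know before trusting results on their own data.

## The recognition premise

A transplanted brassica seedling enjoys a growth head start over the
weeds that germinate around it, so its canopy stands well above both
soil and weeds. With a downward-looking stereo rig, height is
recoverable geometry — unlike color, which fails under field
illumination and green-on-green weed pressure. The pipeline therefore
reconstructs the scene in 3D and finds the crop as the cluster nearest
the camera.

## Stage models

### Rectification

`build_rectification()` computes one rectifying rotation per camera so
that both rectified views share an orientation whose x-axis is the
baseline. The left camera's rotation is built directly: the first row
is the unit baseline (direction to the right camera center,
`-R'T`), the third row balances the two optical axes (the normalized
mean of the left z-axis and the right z-axis expressed in the left
frame), and the second completes the right-handed frame. The right
camera's rectifying rotation follows as `R_rect_left %*% t(R)`. Both
views share intrinsics with the mean of the four focal lengths.
After rectification a point at depth `Z` has disparity exactly
`f·B/Z` and identical rows in both views; the test suite checks
≥ 99 % of synthetic correspondences align to < 0.5 px on a distorted,
2°-rotated rig.

Output sizing is a policy, not a fixed rule: `preserve_all` (default)
sizes the raster so every valid source pixel of either view survives,
which is why a distorted, slightly rotated 640×480 rig typically
rectifies to something larger (the bundled field study's rig grew to
791×547); `crop_valid` instead keeps the inner rectangle covered by
both views. Resampling is bilinear, with black fill outside the
source; pixel centers sit at integer coordinates, origin top-left,
0-based.

### Stereo matching

The matching cost is a windowed mean of absolute (SAD) or squared
(SSD) gray-level differences, in 8-bit gray levels, with border and
out-of-range samples excluded and per-pixel normalization by the
count of contributing samples. Window defaults: 15×15 for SGM, 55×55
for the block-matching baselines (block matching needs a much larger
window before its maps are usable, which is exactly why it loses to
SGM). The disparity range is 0–128 px.

SGM aggregates the cost along 2, 4 or 8 scan-line directions with the
standard small/large penalty recursion (`P1 = 8`, `P2 = 32` gray
levels by default; the path order is horizontal, vertical, then
diagonal pairs). Winner-take-all follows, with a three-point parabolic
subpixel fit (ties break to the smaller disparity), a uniqueness check
(the best cost must beat every candidate further than one step by a
relative margin, default 5 %), and a left-right consistency check
(tolerance 1 px; the right-view disparity is computed from the same
aggregated volume). Pixels failing any check are invalid and become
non-finite 3D points downstream.

The aggregation is exposed separately (`sgm_aggregate()`) and is
checked for exact equality against an independent brute-force
recursion on small instances — integral costs make the comparison
exact, not approximate.

### Reconstruction and down-sampling

Reprojection is the pinhole inverse `Z = f·B/d` in the left rectified
frame, millimetres, z away from the camera. The dense cloud always
has `width × height` rows (one per pixel; invalid pixels are
non-finite), so at the field study's 791×547 rectified resolution the
dense cloud is exactly 432,677 points. `remove_invalid()` keeps the
finite rows in order; afterwards the cloud is treated as unordered.

The non-uniform grid filter reduces the cloud to a fixed budget
(default 4096) by octree splitting: always split the occupied box with
the most points (ties to the lowest Morton path) until the number of
occupied leaves equals the budget, then emit one representative per
leaf — by default the member point nearest the leaf centroid, so
colors remain authentic samples. When the final split would overshoot,
the largest octants become leaves and the remainder are pooled, so the
output count lands exactly on the budget. Dense regions get fine
boxes, sparse regions coarse ones; the budget is hit exactly whenever
the input exceeds it.

### Mixture clustering and crop selection

The down-sampled cloud is modeled as a K-component Gaussian mixture
over raw 3D coordinates (no color features: the recognition premise is
geometric). EM alternates responsibilities (Bayes' rule) with
weighted-moment updates until the relative log-likelihood change drops
below `1e-6` or 200 iterations. All densities are evaluated in log
space via Cholesky factors, responsibilities via log-sum-exp, so
millimetre-scale data does not underflow. Covariance eigenvalues are
floored at `1e-6 mm²`: a collapsing component flattens to the floor
instead of raising an error.

`K = 10` by default: in field scenes roughly one component covers the
canopy and the rest absorb soil patches, furrows and weed clumps. EM
is initialized by k-means++ seeding; because EM only finds local
optima, `gmm_fit()` runs `n_init = 5` short (30-iteration) seeded
starts and continues the best by log-likelihood — the standard
short-run multi-start strategy. With it, repeated fits of the same
field cloud land on the same crop component with weight differences
at the `1e-3` level or below.

The crop is selected as the non-empty component whose member points
have the smallest mean z — nearest the downward-looking camera. The
rule is configurable (`largest_weight` is also available) because
height advantage is a premise about transplanted crops, not a law;
for crops shorter than their weeds the default rule is wrong by
construction.

### Outlier filtering

The selected component is cleaned by the k-nearest-neighbor criterion:
remove points whose mean distance to their `k = 10` nearest neighbors
exceeds `mean + α·sd` (α = 1) of that statistic over the component.
Note a statistical property of this rule: on a perfectly clean,
compact cluster it still removes the upper tail — typically 10–15 % of
points, concentrated where the cluster is sparsest (leaf tips). It is
a denoiser for clouds with genuine stragglers, not a no-op on clean
data; the evaluation protocol below accounts for this.

### Evaluation

`sensitivity()` is the standard recall on areas:
`|reference ∩ predicted| / |reference|`, with the *reference* (e.g.
manually segmented) area as denominator. Top-view masks come from
orthographic rasterization along z. Two raster parameters matter:

* **Resolution.** For dense clouds 1 mm/px is fine. For a 4096-point
  cloud the inter-point spacing is ~7–10 mm, so the end-to-end
  evaluation uses 10 mm cells — a raster finer than the point spacing
  makes any sparse footprint spuriously porous.
* **Dilation.** Each down-sampled point represents its whole octree
  leaf, not a single spot; `dilate_radius = 1` cell restores that
  represented footprint before the closing. Morphological closing
  alone cannot do this: it never thickens isolated pixels, only
  bridges nearby ones. (Marker-rendered scatter top views, the usual
  way such clouds are displayed and binarized, implicitly perform the
  same dilation.)

The canopy envelope box is the axis-aligned min–max extent per axis;
its volume is the product. Because extents are min–max, a single
straggler sets the box; compare boxes only after outlier filtering.

## The synthetic scene generator

No field imagery ships with the package, so `render_stereo_pair()`
builds fully labeled scenes that emulate the geometry and statistics
of transplanted-seedling fields:

* **Soil**: a plane at 800 mm (the rig's working distance is
  500–2000 mm), viewed 10° off-nadir as a handheld rig would;
  clod-scale roughness (±8 mm at 60–150 mm scales), broad bed
  undulation (±25 mm at 300–600 mm), and sinusoidal cultivation
  furrows (±20 mm, 250 mm wavelength) left by a bed former. The
  background's depth structure matters: it is what the other nine
  mixture components model.
* **Crop**: a rosette canopy of radius 90 mm (≈ 8–9 % of the image, a
  recently transplanted seedling) and height 180 mm. The visible
  surface is an elevated, roughly flat-topped leaf crown: a
  spherical-cap profile clipped below at 0.7 of the height — the
  crown hangs above the soil, so its edge is a depth step that
  produces the occlusion ring ("black boundary") separating crop from
  background in the reconstruction — modulated by leaf-scale
  (30–70 mm) height variation of amplitude 0.35, and bounded by a
  6-lobed star footprint so the top-view density peaks at the center
  and decays outward, as for a real rosette whose outer leaf tips are
  separated by visible soil.
* **Weeds**: 24 hemispherical bumps, 20–60 mm tall — below the crop's
  lowest visible canopy, which is the height-advantage premise; the
  generator rejects specs that violate it.
* **Rendering**: both views sample one world-anchored band-limited
  texture (brown soil, green plant/weeds), so correspondences agree
  up to the additive pixel noise (σ = 2 gray levels); per-pixel
  ray–surface intersection is a damped fixed-point iteration, and the
  recorded ground-truth disparity `f·B/Z` is exact for the rendered
  geometry. A clipped brightness gain emulates overexposure.

What the generator does **not** emulate: real leaf texture and specular
highlights, genuinely mismatched SGM regions (repetitive or saturated
texture), wind motion between exposures, and rolling-shutter or
synchronization artifacts. Consequently the synthetic pipeline's
failure modes are geometric (occlusion, sparsity), not photometric;
passing tests show the chain of geometry, clustering and filtering is
correct, not that matching survives every field pathology.

Problem sizes used by the test suite and acceptance script: one
640×480 end-to-end scene (about 20 s), 32×32 SGM oracle instances,
2000-point clouds for EM parameter recovery (20 seeded trials), 200
points for the KNN oracle, and 10 repeated mixture fits for the
stability check.

## Numerical choices

* Ties in winner-take-all go to the smaller disparity; octree ties to
  the lowest Morton path; equal-mean-z components to the lower index.
  Everything is deterministic given the seeds.
* Disparity export is 16-bit fixed point at 1/16 px (high/low bytes in
  two PNG channels), lossless to 1/32 px.
* PLY/PCD writers use float32 coordinates (the formats' convention);
  round trips are exact at float precision.
* `with_seed()` restores the session RNG state, so seeded fits do not
  perturb user code.

## Known limitations

* The height-advantage rule selects exactly one mixture component; a
  crop whose canopy splits across two components (e.g. two plants in
  frame, or K much larger than 10) needs per-component selection and
  merging, which is out of scope here.
* Sensitivity is recall only; the package reports predicted and
  intersection areas so precision-style quantities can be derived, but
  the headline metric ignores false positives outside the reference.
* The envelope box is axis-aligned in the camera frame; a tilted rig
  tilts the box relative to the plant's natural axes.
* Block matching at the 55×55 window is slow by design (it is the
  baseline the SGM comparison needs, not a production path).
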