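# seedling3d

Recognition of transplanted crop seedlings (broccoli, cabbage and
similar brassicas) in binocular field images.

Color-based 2D segmentation fails in the field: illumination is
uncontrolled, the soil background is cluttered, and weeds share the
crop's green. What a transplanted seedling reliably has is a **height
advantage** — its growth head start puts the canopy well above both
soil and weeds. `seedling3d` exploits that advantage with a stereo
pipeline:

1. **Epipolar rectification** of the binocular pair (Bouguet-style:
   both cameras rotated onto a shared frame with the baseline as the
   x-axis), so matching becomes a 1D scan-line search.
2. **Semi-global matching (SGM)**: a windowed SAD cost
   `C(p, d)` aggregated along 8 scan-line directions with
   `L_r(p,d) = C(p,d) + min(L_r(p-r,d), L_r(p-r,d±1)+P1,
   min_k L_r(p-r,k)+P2) − min_k L_r(p-r,k)`,
   winner-take-all with subpixel refinement, uniqueness and left-right
   checks (SAD/SSD block matchers are included as baselines).
3. **3D reconstruction**: `Z = f·B/d`, `X = (u−c_x)Z/f`,
   `Y = (v−c_y)Z/f` per valid pixel, colors from the left view;
   non-finite (invalid) points removed.
4. **Non-uniform grid down-sampling** to a fixed 4096-point budget by
   octree splitting (always the most populated box next), preserving
   structure while bounding the clustering cost.
5. **Gaussian mixture clustering** by EM on the 3D coordinates,
   `p(x) = Σ_k π_k N(x | μ_k, Σ_k)` with `K = 10`: responsibilities by
   Bayes' rule (E-step), weighted-moment updates (M-step), log-space
   densities, multi-start initialization.
6. **Crop selection** — the component whose members are nearest the
   downward-looking camera (smallest mean z) is the seedling.
7. **KNN outlier filtering**: points whose mean distance to their 10
   nearest neighbors exceeds `mean + α·sd` of that statistic are
   dropped.

Evaluation utilities compute **top-view sensitivity**
(`|reference ∩ predicted| / |reference|`) against a reference mask and
the **canopy envelope box** (axis-aligned extents and volume). A fully
labeled **synthetic field-scene generator** (textured furrowed soil,
weed bumps, a lobed rosette canopy, exact per-pixel disparity ground
truth) makes every stage testable without field data.

## Worked example

```r
library(seedling3d)

spec  <- scene_spec(texture_seed = 0)      # default 640x480 field scene
scene <- render_stereo_pair(spec)
res   <- run_pipeline(scene$left, scene$right, spec$calib)
print(res)
#> Seedling recognition pipeline
#>   dense 307200 -> finite 276437 -> sparse 4096 -> crop 359 -> filtered 310
#>   crop component 1 (pi = 0.0876); envelope 158x130x53 mm
#>   17.45 s total

scene_crop_sensitivity(res$crop, scene, spec)
#> Sensitivity 95.79% (reference 214 px, predicted 250 px, overlap 205 px)
```

Reading the output: the 640×480 pair reprojects to 307,200 dense
points, of which 276,437 survive invalid-point removal; the octree
filter reduces them to exactly 4096; the mixture assigns 359 points
(weight π = 0.0876) to the component nearest the camera — the
seedling — and the KNN filter keeps 310 of them. The recognized
footprint covers 95.8% of the true canopy's top view, and the canopy
envelope box is ~158 × 130 × 53 mm.

`summary(res$gmm)` shows the full mixture (one canopy component at
mean z ≈ 699 mm against soil/weed components at 740–815 mm);
`plot(res$gmm)` draws the labeled cloud. A thin command-line front end
with `simulate`, `run`, `match` and `evaluate` subcommands is
installed at `system.file("cli", "seedling3d.R", package =
"seedling3d")`.

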