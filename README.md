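# stemleaf3d

3-D plant phenotyping from point clouds, end to end: extract a dense cloud
from an implicit radiance field by expected-depth volume rendering,
preprocess it (Otsu colour-threshold ground removal, statistical outlier
filtering, farthest point sampling, normal estimation), segment stem from
leaf points with a lightweight encoder–decoder point-cloud network, and
measure four phenotypic traits — stem height, stem diameter, leaf length
and leaf width — from the segmented cloud. A procedural generator of
labelled plants with analytic ground truth makes the whole pipeline
testable on a laptop, without any external dataset.

The package is aimed at plant-phenotyping researchers who want a
reproducible, dependency-light reference implementation of this pipeline
in R, and at method developers who need analytic fixtures for each stage.

## The methods in brief

**Depth from an implicit field.** For a ray sampled at depths `d_i` with
intervals `δ_i` through a density field `σ`, discrete volume rendering
gives `α_i = 1 − exp(−σ_i δ_i)`, `T_i = Π_{j<i}(1−α_j)`, weights
`w_i = T_i α_i`, and the surface depth `t* = Σ d_i w_i / Σ w_i`,
back-projected as `p = o + t* d`. Rays whose accumulated weight stays
below a floor (default 0.5) are dropped.

**Segmentation network.** Four encoder stages (each: farthest-point
sampling at rate 0.5; a local branch of grouped MLP + max-pool + residual
over ball-query neighbourhoods, k = 32; a global relative-spatial-attention
branch; a learnable scalar gate fusing the two; channel attention from
pooled mean/sd statistics), mirrored by four decoder stages
(inverse-distance interpolation, skip fusion, the same residual block over
16-NN neighbourhoods, rectified-mean edge features), and a two-layer head.
The frozen reference configuration has 1.33 M learnable parameters and an
analytic forward cost of 4.75 GFLOPs at 2048 input points. Training uses a
polynomial focal loss `mean(L_CE (1−P_t)^γ + ε (1−P_t)^{γ+1})` with
sigmoid one-vs-rest probabilities, AdamW, and ×0.1 learning-rate decay at
epochs 210 and 270. Everything runs on a small reverse-mode autodiff tape
included in the package; neighbourhood search is compiled C++.

**Traits.** The stem's principal axis is rotated to +z; stem height is the
axial extent, stem diameter twice the median absolute residual of a plane
fitted to the basal quarter. Leaves are split into instances by 10-NN
graph connectivity; each leaf is sliced along its principal axis, chords
across each slice are refined by points projected onto the surface, and
smoothed polylines give the width (maximum over slices) and the length
(through the slice midpoints). Accuracy is scored by R² and RMSE.

## Worked example

Generate a labelled plant, recover its traits, and compare with the
generator's analytic ground truth:

```r
library(stemleaf3d)

out <- generatePlant(plantSpec(
  stem_radius = 1, stem_length = 50, stem_tilt_deg = 10,
  leaves = list(
    leafSpec(attach_height_frac = 0.5, azimuth_deg = 20,
             R = 40, sweep_deg = 80, max_width = 7, taper = "sine"),
    leafSpec(attach_height_frac = 0.8, azimuth_deg = 200,
             R = 35, sweep_deg = 70, max_width = 6, taper = "sine")),
  points_per_organ = 512, seed = 11))

out$cloud
#> PointCloud with 1536 points (z-up frame)
#>   channels: normals, colors[byte], labels{0,1}
#>   extent: x[-20.4, 47.4] y[-11.9, 14.5] z[0.0707, 67.6]

extractTraits(out$cloud)
#> TraitReport: stem height 49.887, stem diameter 5.160, 2 leaves
#>   leaf 1: length 55.145, width 6.961
#>   leaf 2: length 42.601, width 5.954

unlist(out$traits)
#>   stem_height stem_diameter leaf_lengths1 leaf_lengths2  leaf_widths1
#>      50.00000       2.00000      55.85054      42.76057       7.00000
#>  leaf_widths2
#>       6.00000
```

The stem height and the two leaf lengths/widths land within a few percent
of the analytic values (the 50-long stem measures 49.89 because the
lateral surface is sampled, not the end caps). The reported stem
"diameter" is the published procedural measure — twice the median
absolute residual of a basal plane fit — which for an aligned stem tracks
the basal axial spread rather than the geometric diameter 2; the package
validates it against a brute-force re-derivation of the same procedure
(see the methods vignette).

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/stemleaf3d.R`): `synth`, `preprocess`, `nerf-extract`, `train`,
`segment`, `traits` and `eval-traits` subcommands.

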