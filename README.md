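# thermomap3d

Tools for building **3D thermographic maps of transtibial residual
limbs**: a set of 2D infrared images (320 x 240 temperature rasters,
degC) taken around the limb on a rotating platform is registered onto a
3D surface scan, skin temperatures are recovered per mesh vertex, and
two acquisition conditions (post-walk vs rest) are reduced to a single
differential 3D map. Hollow-cube thermal fiducials — visible both in the
infrared images and in the geometry — make the registration automatic
and give an intrinsic, per-marker estimate of the registration error.

The intended users are researchers and prosthetists who want objective
temperature maps of the stump-socket interface (hot spots signal
mechanical stress and impaired vascularisation) without relying on
manual 2D image inspection.

## Method

Per condition, four branches:

1. **Encode** — each raster is clipped to the anchors
   [28, 37] degC, normalised to `x`, and coloured with a 256-level jet
   palette `r(x)=clamp(1.5-|4x-3|)`, `g(x)=clamp(1.5-|4x-2|)`,
   `b(x)=clamp(1.5-|4x-1|)` (8-bit).
2. **Invert the colormap** — all observed (temperature, rgb) pairs form
   a deduplicated 1:1 table (temperatures sharing one colour are
   averaged); half the rows train a grown Gaussian radial-basis model,
   the other half validate it until its held-out MSE is at or below
   1e-4 degC^2. The model maps *any* 8-bit colour — including blends
   created later by texturing — to a temperature.
3. **Register and texture** — marker blobs (the cubes image ~26 degC
   against >28 degC skin) initialise each view's 6-DoF pose via
   perspective-n-point; the pose is refined by maximising the mutual
   information between the frame and a rendered Lambertian shading of
   the mesh. Visible vertices (frustum + facing + ray-cast occlusion)
   receive bilinear samples of the encoded images, blended across views
   with cosine weights.
4. **Decode** — vertex colours become vertex temperatures; the result is
   a PLY mesh with a float `temperature` property.

The differential stage subtracts the two conditions per vertex and
colour-codes the difference over its observed range. Around each
marker, the near-zero difference "halo" is segmented
(|dT| <= 0.3 degC within 15 mm) and the distance from the marker centre
to the halo centroid is that marker's misalignment; the median over
markers is the workflow's accuracy figure. Camera calibration
(chessboard homographies + joint Levenberg-Marquardt over intrinsics,
two radial distortion terms and poses) is accepted below 1 px mean
reprojection error.

A fully synthetic scene generator (parametric limb, cube fiducials,
Gaussian hot-spot fields, distorted-pinhole z-buffer renderer with
0.07 degC sensor noise) stands in for the hardware, so the entire chain
is testable end to end.

## Worked example

```r
library(thermomap3d)

demo <- run_demo(seed = 1)       # simulate + both conditions + differential
print(demo$stats)
#> <registration_error_stats> median 2.48 mm (sd 0.69, range 1.21-2.85 mm,
#>   5 markers, 0 missing)

summarize_hotspots(demo$post_walk$mesh, threshold = 34)
#>   component n_vertices     area_m2   peak_c
#> 1         1       1002 0.005802186 35.46377
#> 2         2        512 0.003092192 35.83427
```

`run_demo()` builds the default synthetic scene (7 views per condition
at 45-degree steps and 120 cm, 5 markers, NETD-level noise), runs both
conditions through branches A-D and the differential stage. The printed
median — 2.48 mm here — is the combined two-condition registration
error measured from the marker halos; values of 2-3 mm are at the scale
of the mesh vertex spacing and well below the width of socket
adjustment tools. The two hot-spot components are the simulated
suprapatellar and flap warm regions. `demo$diff` holds the per-vertex
differential map (post-walk minus rest: +1.4 to +2.3 degC across most
skin, near 0 on the markers), and `write_differential_ply()` saves it
for MeshLab viewing.

A thin CLI over the same functions ships in `inst/cli/thermomap3d`
(subcommands `simulate`, `demo`, `diff`).

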