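---
title: "Mapping 2D infrared thermography onto 3D residual-limb scans: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping 2D infrared thermography onto 3D residual-limb scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After a transtibial amputation, the fit between the residual limb and the
prosthetic socket decides much of the wearer's comfort and skin health.
Skin temperature is a usable proxy for mechanical stress and impaired
vascularisation, but a thermal camera only delivers 2D views: relating
hot spots across seven or more separate images of a roughly conical limb
is error-prone. This package implements a workflow that fuses a set of 2D
thermal images (320 x 240 temperature rasters in degrees Celsius) with a
3D surface scan of the limb, producing a per-vertex 3D temperature map
for each acquisition condition (e.g. immediately after walking and after
rest), a differential map of their per-vertex difference, and an
intrinsic estimate of the registration error derived from thermal
fiducial markers.

The workflow has four processing branches per condition:

* **A — encoding.** Each temperature raster is colour-coded with a jet
  colormap whose saturation anchors are fixed at 28 and 37 degC.
* **B — colormap inversion.** A temperature-to-colour table is built from
  the rasters and inverted with a small grown radial-basis model, so that
  *any* 8-bit colour — including blends that the texturing step invents —
  can be turned back into a temperature.
* **C — registration and texturing.** Each encoded image is registered to
  the mesh (fiducial-based pose initialisation, mutual-information
  refinement) and its colours are transferred to the visible vertices.
* **D — decoding.** Vertex colours become vertex temperatures; the result
  is a PLY mesh with a per-vertex `temperature` property.

## Fiducial markers and the accuracy metric

Hollow ABS cubes (5 mm edge on a 14 mm x 0.5 mm base) are visible both in
the thermal image — ambient air flows through them, so they image several
degrees below skin — and in the geometry scan. Because a marker's
temperature is (almost) the same in both conditions, the differential map
shows a near-zero "halo" on top of each marker while the surrounding skin
changes by a degree or more. The displacement between a marker's known
centre and its halo centroid measures the *combined* registration error
of both conditions; the median over markers is the workflow's headline
accuracy number.

Two properties of this metric are worth keeping in mind when reading the
numbers. First, the halo lives on the visible outer surface of the marker
hardware while the reference point is the cube's volumetric centre, so
even a perfectly registered scene leaves a residual of roughly the cube
half-edge (2.5 mm) projected onto the centre-to-centroid direction; the
metric is therefore conservative. Second, the halo centroid is computed
from mesh vertices spaced a few millimetres apart, which quantises the
centroid at a similar scale.

## Camera model and calibration

The thermal camera is a standard pinhole with two radial distortion
terms, `x_d = x_n (1 + k1 r^2 + k2 r^4)`, zero skew and zero tangential
distortion; the defaults of `camera_model()` are the calibrated
parameters of the acquisition camera (focal 736.5/742.4 px, principal
point (274.4, 145.2), k = (-0.1004, -1.0318) at 320 x 240). Calibration
(`calibrate_camera()`) uses views of a planar chessboard of 30 mm
squares on a 300 x 180 mm board: normalised-DLT homographies, the
closed-form absolute-conic estimate of the intrinsic matrix, per-view
extrinsics from the homography columns, then one joint
Levenberg-Marquardt refinement of intrinsics, distortion and all poses.
A calibration is accepted when the mean reprojection error is below one
pixel.

A note on precision: with this camera's narrow field of view (about 24
degrees), twenty views at up to 45 degrees inclination and 0.1 px corner
noise, the Fisher information limits the principal point to a standard
deviation of roughly 1.3-1.9 px and `k1` to about 0.006 — the focal
lengths are recovered to a fraction of a percent, but the principal point
and distortion coefficients are intrinsically noisier at this geometry no
matter the estimator. The implemented estimator matches these bounds
empirically.

## Colormap inversion

Encoding quantises `x = (T - 28)/9` onto 256 palette levels of the
continuous jet formula `r(x) = clamp(1.5 - |4x - 3|)`, `g(x) = clamp(1.5
- |4x - 2|)`, `b(x) = clamp(1.5 - |4x - 1|)`, scaled to 8 bits. The
colour table pairs each observed colour with the mean of the (0.01 degC
resolution) temperatures that produced it, giving a strictly increasing
1:1 table.

Inversion trains on a random half of the table (seeded split) and
validates on the other half, growing Gaussian radial-basis centres at the
worst-residual training row until the held-out mean squared error drops
below 1e-4 degC^2. The regression input is *not* the raw rgb triple: the
jet arc in rgb space has right-angle bends, and its 8-bit quantisation
advances by 3, 4 or 5 counts per level, so any smooth interpolant over
rgb coordinates carries an irreducible held-out error of several
hundredths of a degree around the bends and split gaps — orders of
magnitude above the stopping criterion. Since the encoder is the
package's own, each query colour is first projected onto the known
palette polyline, yielding a fractional palette coordinate `u` in [0, 1]
that is exact for palette colours and maps a 50/50 blend of two adjacent
colours onto their midpoint; the RBF (plus a linear tail) is grown in
`u`. This keeps the training/validation protocol intact while making the
problem well-posed, and it gives blended off-arc colours the natural
interpretation of their nearest on-arc colour. Training additionally
requires the worst held-out residual to stay below 1.5 * sqrt(1e-4) so
the per-level round-trip bound holds pointwise, not only on average.

## Registration

Marker blobs are segmented by thresholding the frame within 1 degC of
the marker temperature (26 degC by default), labelling connected
components and discarding those under 3 px. Blobs are associated to mesh
marker centres by nearest projection under the nominal rotating-platform
pose for that view (the azimuth is known from the view index). With at
least three matched markers, `estimate_pose_from_fiducials()` solves the
perspective-n-point problem: undistorted pixel rays, orthogonal-iteration
initialisation (alternating ray depths with an absolute-orientation
fit), Levenberg-Marquardt polish, and a pool of canonical look-at
restarts that removes the mirror-pose failure mode of the alternation.
Three points determine the pose exactly (up to the classical multi-al
solution ambiguity, which the restart pool plus closeness to the
initialisation resolves), so any systematic blob-centroid bias — the
centroid of the cube's *visible* faces is not quite the projection of
its centre — maps one-to-one into pose error, almost entirely along
depth. The pipeline therefore fits a maximum-a-posteriori pose: the
nominal platform pose enters as a prior (2 degrees / 10 mm standard
deviations), which is legitimate because the platform fixes the
acquisition geometry by construction. Views with fewer than three
matched markers use the platform pose directly. At 120 cm with markers
spreading 10-20 cm, 1 px of centroid noise leaves a few millimetres of
in-image-plane error but one to two centimetres of unregularised depth
uncertainty; the halo metric is insensitive to depth, which is also the
component the socket-fitting application cares least about.

Refinement maximises the mutual information between the thermal frame
and a rendered, pose-dependent surface attribute. The attribute is
Lambertian shading (cosine between vertex normal and view direction):
it is pose-sensitive, correlates with the thermal shading of a curved
limb, and needs no temperature knowledge. MI uses a 32 x 32 joint
histogram over the rendered silhouette of the *initial* pose; keeping
the evaluation mask fixed is deliberate — if the mask tracked the
candidate pose, shrinking the silhouette would discard the mixed
boundary pixels and spuriously inflate MI (the classic overlap
pathology of MI registration). The optimiser is Nelder-Mead over six
pose increments (axis-angle and translation) with one restart; the
initial simplex steps (0.01 rad, 2 mm) are chosen to be large enough to
cross the sub-pixel plateaus of a histogram-based objective. The
refined MI is never below the initial pose's. A final consistency gate
protects against the failure mode where a marginal MI gain buys a
millimetre-scale pose drift: if the refined pose degrades the fiducial
blob reprojection by more than one pixel, the fiducial pose is kept —
the refinement may sharpen the fiducial solution but not contradict it.

## Texturing

A vertex is visible in a view when its projection lies inside the image,
it faces the camera, and the ray from the vertex to the camera centre is
unobstructed (grid-accelerated ray casting, eps = 1e-5 m). Colour
transfer samples each encoded image bilinearly at the vertex projection
and blends across views with normalised cosine weights — this blending
deliberately reproduces the seam smoothing that generates off-table
colours, which is the reason branch D needs a model rather than a lookup
table. Three guards keep the samples honest: background taps are excluded
via a foreground mask (frame temperature above 24.5 degC, midway between
ambient and marker), views at incidence beyond ~78 degrees (cosine below
0.2) do not contribute, and skin vertices never sample pixels inside a
marker's projected footprint (9 mm radius), while vertices on the marker
hardware are textured in a second pass restricted to marker-temperature
pixels — so both conditions decode the marker patch consistently and the
differential halo is supported by the whole patch rather than a few
lucky vertices.
Vertices no view can see keep the reserved sentinel colour (0,0,0) and
decode to `NA`.

Mesh cleaning (`clean_mesh()`) mirrors scan post-processing: largest
connected component, removal of interior vertices (no escaping probe ray
along six spread directions — deliberately off the coordinate axes,
where exact rays can thread through shared vertices of symmetric
meshes), and quadric edge-collapse decimation with a link-condition
check, which preserves topology while reducing a ~10^6-vertex scan to
the ~16k-vertex working resolution.

## The synthetic scene

Every quantitative claim is validated on synthetic scenes built by
`simulate_scene()`: a tapered cone (5 cm proximal, 4 cm distal radius,
20 cm long) with a hemispherical distal cap and a small seeded low-order
asymmetry, five cube fiducials at spread heights and azimuths, and seven
camera poses at 45-degree steps, 120 cm from the limb axis. The rest
condition is 31 degC skin with distal cooling and three residual warm
areas; post-walk is uniformly ~1.4 degC warmer with the same warm areas
intensified towards 36 degC — so the skin difference is at least 1.2
degC everywhere while markers stay identical, making halos
well-defined. Markers render at a fixed 26 degC in both conditions
(the hollow cube images ambient air; simulating the actual airflow
is out of scope — visibility in the thermal image is all the
registration needs). Temperature bumps use chordal rather than geodesic
distance, acceptable because spot radii (2-3 cm) are small against the
limb circumference. Rendering projects vertices through the distorted
camera and rasterises with a perspective-correct z-buffer; sensor noise
is additive Gaussian at the camera's NETD (0.07 degC).

What the synthetic scene does *not* emulate: emissivity variation and
angular dependence, reflected ambient radiation, motion between views,
scan reconstruction artefacts, and soft-tissue deformation between
conditions. Passing the synthetic acceptance suite therefore shows the
*processing chain* is correct and self-consistent at realistic noise
levels, not that a clinical acquisition will reach the same accuracy.

With five markers and seven views spanning 270 degrees, some views see
only two markers — geometrically unavoidable, since the frontal and the
back view share no marker within their ~160-degree visibility windows;
those views fall back to the platform-pose initialisation, which is the
situation the real rotating platform provides.

Because marker patches image below the 28 degC anchor, their encoded
colour saturates at the first palette row and their temperature is not
recoverable by construction; temperature-recovery figures are therefore
reported over skin vertices at least 8 mm from any marker centre.

## Problem sizes and runtime

Default sizes are the study's own: 240 x 320 rasters, 7 views per
condition, 5 markers, ~16k mesh vertices (generated at ~19k including
marker geometry), 256-level colormap, 20 calibration views of a 9 x 5
corner grid. The full two-condition demo with MI refinement runs in
about two minutes on one CPU; unit tests use a 4k-vertex scene. The
decimation check builds a 10^6-vertex sphere and reduces it to 16k.

## Known limitations

* Rigid registration only; the limb is assumed identical across views
  and conditions (the rotating platform is designed to make this hold).
* The MI attribute (Lambertian shading) is a proxy; with very uniform
  skin temperature and little geometric relief the MI surface flattens
  and refinement falls back to the fiducial pose (its score never drops
  below the initial pose's).
* The colormap inverse is specific to the package's own encoder; rasters
  encoded with a different palette need a matching `colormap_spec`.
* Marker temperature recovery is impossible by design (saturated); only
  marker geometry and halo position carry information.
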