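#' Synthetic limb scene: specifications
#'
#' Parametric stand-ins for the scanned residual limb and its thermal
#' fiducial markers, so the whole pipeline can be exercised and validated
#' without camera or scanner hardware.
#'
#' `limb_spec()` describes a tapered cone (proximal radius at the top,
#' distal at the bottom) closed by a hemispherical distal cap — the gross
#' shape of a transtibial residual limb. `marker_spec()` describes the
#' hollow-cube fiducials: a 5 mm cube on a 14 mm x 0.5 mm base, placed on
#' the surface at (axial fraction, azimuth) positions.
#'
#' @param length limb length, m (default 0.20).
#' @param proximal_radius,distal_radius radii, m (defaults 0.05 / 0.04).
#' @param mesh_resolution target vertex count (default 16000, the working
#'   resolution of the cleaned scan).
#' @return A `limb_spec` / `marker_spec` list.
#' @export
limb_spec <- function(length = 0.20, proximal_radius = 0.05,
                      distal_radius = 0.04, mesh_resolution = 16000L) {
  stopifnot(length > 0, proximal_radius > 0, distal_radius > 0)
  structure(list(length = length, proximal_radius = proximal_radius,
                 distal_radius = distal_radius,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "limb_spec")
}

#' @rdname limb_spec
#' @param cube_edge_mm cube edge, mm (default 5).
#' @param base_diameter_mm,base_thickness_mm base disc geometry, mm
#'   (defaults 14 and 0.5).
#' @param placements data.frame with columns `axial` (fraction of limb
#'   length, 0 = distal) and `azimuth_deg`; the default places 5 markers
#'   spread in height and azimuth.
#' @param marker_temperature apparent temperature of the hollow cubes in
#'   the thermal image, degC (default 26: ambient air flows through the
#'   cube, so it images well below skin).
#' @export
marker_spec <- function(cube_edge_mm = 5, base_diameter_mm = 14,
                        base_thickness_mm = 0.5,
                        placements = data.frame(
                          axial = c(0.25, 0.55, 0.40, 0.70, 0.30),
                          azimuth_deg = c(0, 72, 144, 216, 288)),
                        marker_temperature = 26) {
  stopifnot(cube_edge_mm > 0, base_diameter_mm > 0, base_thickness_mm >= 0,
            all(c("axial", "azimuth_deg") %in% names(placements)))
  structure(list(cube_edge_mm = cube_edge_mm,
                 base_diameter_mm = base_diameter_mm,
                 base_thickness_mm = base_thickness_mm,
                 placements = placements,
                 marker_temperature = marker_temperature),
            class = "marker_spec")
}

#' Smooth skin-temperature field specification
#'
#' A base temperature plus localised Gaussian hot spots at surface
#' positions given as (axial fraction, azimuth); peak amplitudes in degC
#' and radii in metres. Composed values must stay within the colormap
#' anchors \[28, 37\] degC on skin; marker vertices are overridden with the
#' marker temperature in both conditions.
#'
#' @param base_temperature base skin temperature, degC.
#' @param spots data.frame with columns `axial`, `azimuth_deg`, `peak`
#'   (degC above base) and `radius` (m); may be empty.
#' @param condition_label `"rest"` or `"post_walk"`.
#' @return A `temperature_field` list.
#' @export
temperature_field <- function(base_temperature,
                              spots = data.frame(axial = numeric(),
                                                 azimuth_deg = numeric(),
                                                 peak = numeric(),
                                                 radius = numeric()),
                              condition_label = "rest") {
  structure(list(base_temperature = base_temperature, spots = spots,
                 condition_label = condition_label),
            class = "temperature_field")
}

limb_radius_at <- function(spec, z) {
  spec$distal_radius +
    (spec$proximal_radius - spec$distal_radius) * z / spec$length
}

limb_surface_point <- function(spec, axial, azimuth_deg, offset = 0) {
  if (axial <= 0)  # distal pole of the hemispherical cap
    return(c(0, 0, -spec$distal_radius - offset))
  z <- axial * spec$length
  rho <- limb_radius_at(spec, z) + offset
  a <- azimuth_deg * pi / 180
  c(rho * cos(a), rho * sin(a), z)
}

#' Build the synthetic limb mesh with cube fiducials
#'
#' Generates a watertight tapered-cone-plus-hemispherical-cap limb surface
#' at approximately the requested resolution and attaches the fiducial
#' markers (base disc + cube, both closed meshes) at their surface
#' positions along the outward radial direction. Cube centres sit at
#' `radius(z) + base_thickness + edge/2` from the limb axis. Marker
#' vertices are flagged, and the recorded marker centres are the cube
#' centres.
#'
#' @param spec a [limb_spec()].
#' @param markers a [marker_spec()].
#' @param seed RNG seed (the surface gets a small seeded bumpy modulation
#'   so renders are not trivially symmetric).
#' @return A [limb_mesh()] with `marker_vertex` flags and attribute
#'   `marker_centers` (k x 3 matrix, metres).
#' @export
make_limb_mesh <- function(spec = limb_spec(), markers = marker_spec(),
                           seed = 1L) {
  set.seed(seed)
  L <- spec$length; rd <- spec$distal_radius; rp <- spec$proximal_radius
  rbar <- (rd + rp) / 2
  a_cone <- 2 * pi * rbar * L
  a_cap <- 2 * pi * rd^2
  a_disk <- pi * rp^2
  h <- sqrt((a_cone + a_cap + a_disk) / spec$mesh_resolution)
  counts <- function(h) {
    list(ntheta = max(12L, round(2 * pi * rbar / h)),
         nz = max(4L, round(L / h)),
         ncap = max(3L, round(rd * pi / 2 / h)),
         ndisk = max(2L, round(rp / h) - 1L))
  }
  # rings keep a constant vertex count, so the cap and disk come out
  # denser than the uniform-area estimate; one correction step brings
  # the total back to the requested resolution
  for (i in 1:2) {
    cn <- counts(h)
    total <- cn$ntheta * (cn$nz + cn$ncap + cn$ndisk) + 2
    h <- h * sqrt(total / spec$mesh_resolution)
  }
  cn <- counts(h)
  ntheta <- cn$ntheta; nz <- cn$nz; ncap <- cn$ncap; ndisk <- cn$ndisk

  theta <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  # mild seeded asymmetry: low-order azimuthal/axial modulation (a real
  # limb is not a surface of revolution)
  amp <- stats::runif(3, 0.001, 0.003)
  pha <- stats::runif(3, 0, 2 * pi)
  bump <- function(th, zfrac)
    amp[1] * cos(th + pha[1]) * zfrac +
    amp[2] * cos(2 * th + pha[2]) * (1 - zfrac) +
    amp[3] * sin(th + pha[3]) * zfrac * (1 - zfrac) * 4

  rows <- list(); zs <- numeric(0); rowlen <- integer(0)
  # hemispherical cap: polar angle from pole (phi=0) to equator
  for (i in seq_len(ncap)) {
    phi <- i / ncap * pi / 2
    r <- rd * sin(phi); z <- -rd * cos(phi)
    rows[[length(rows) + 1]] <-
      cbind(r * cos(theta), r * sin(theta), z)
  }
  # cone
  for (i in seq_len(nz)) {
    z <- i / nz * L
    r <- limb_radius_at(spec, z) + bump(theta, z / L)
    rows[[length(rows) + 1]] <- cbind(r * cos(theta), r * sin(theta), z)
  }
  # proximal disk rings (shrinking radius at z = L)
  rtop <- limb_radius_at(spec, L)
  for (i in seq_len(ndisk)) {
    r <- rtop * (1 - i / (ndisk + 1))
    rows[[length(rows) + 1]] <- cbind(r * cos(theta), r * sin(theta), L)
  }
  V <- do.call(rbind, rows)
  nrows <- length(rows)
  south <- nrow(V) + 1L; north <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, -rd), c(0, 0, L))

  idx <- function(row, j) (row - 1L) * ntheta + (j - 1L) %% ntheta + 1L
  F <- vector("list", nrows + 1L)
  # band triangles between consecutive rings, outward winding
  for (row in seq_len(nrows - 1L)) {
    j <- seq_len(ntheta)
    F[[row]] <- rbind(
      cbind(idx(row, j), idx(row, j + 1L), idx(row + 1L, j)),
      cbind(idx(row + 1L, j), idx(row, j + 1L), idx(row + 1L, j + 1L)))
  }
  j <- seq_len(ntheta)
  F[[nrows]] <- cbind(south, idx(1L, j + 1L), idx(1L, j))       # cap pole
  F[[nrows + 1L]] <- cbind(north, idx(nrows, j), idx(nrows, j + 1L))
  F <- do.call(rbind, F)

  marker_flag <- rep(FALSE, nrow(V))
  centers <- NULL
  pl <- markers$placements
  if (nrow(pl) > 0) {
    e <- markers$cube_edge_mm / 1000
    bt <- markers$base_thickness_mm / 1000
    brad <- markers$base_diameter_mm / 2000
    pts <- t(vapply(seq_len(nrow(pl)), function(i)
      limb_surface_point(spec, pl$axial[i], pl$azimuth_deg[i]),
      numeric(3)))
    if (nrow(pl) > 1) {
      dd <- as.matrix(stats::dist(pts))
      diag(dd) <- Inf
      if (min(dd) < 2 * brad)
        stop(sprintf("overlapping marker placements (min spacing %.1f mm < %g mm)",
                     min(dd) * 1000, 2 * brad * 1000), call. = FALSE)
    }
    for (i in seq_len(nrow(pl))) {
      a <- pl$azimuth_deg[i] * pi / 180
      nrm <- c(cos(a), sin(a), 0)            # outward radial direction
      axial_dir <- c(0, 0, 1)
      side <- c(-sin(a), cos(a), 0)
      base0 <- pts[i, ]
      # base disc: octagonal prism of thickness bt
      oct <- seq(0, 2 * pi, length.out = 9)[-9]
      ring <- t(vapply(oct, function(t0)
        base0 + brad * (cos(t0) * axial_dir + sin(t0) * side), numeric(3)))
      vb <- nrow(V)
      V <- rbind(V, ring, sweep(ring, 2, nrm * bt, "+"))
      lo <- vb + 1:8; hi <- vb + 9:16
      Fb <- rbind(
        do.call(rbind, lapply(1:8, function(k) {
          kn <- k %% 8 + 1
          rbind(c(lo[k], lo[kn], hi[k]), c(hi[k], lo[kn], hi[kn]))
        })),
        do.call(rbind, lapply(2:7, function(k)
          c(hi[1], hi[k], hi[k + 1]))),
        do.call(rbind, lapply(2:7, function(k)
          c(lo[1], lo[k + 1], lo[k]))))
      # cube sitting on the base, centred at base + (bt + e/2) * nrm
      ctr <- base0 + (bt + e / 2) * nrm
      sgn <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
      cv <- t(apply(sgn, 1, function(s)
        ctr + (e / 2) * (s[1] * nrm + s[2] * axial_dir + s[3] * side)))
      vc <- nrow(V)
      V <- rbind(V, cv)
      # 12 triangles of the cube (unit-cube template, 1-based corners in
      # the (a,b,c) = (-,-,-),(+,-,-),(-,+,-),(+,+,-),(-,-,+),(+,-,+),
      # (-,+,+),(+,+,+) order of expand.grid)
      cube_tris <- matrix(c(
        1, 3, 2, 2, 3, 4,   # a = -
        5, 6, 7, 6, 8, 7,   # a = + (outward face)
        1, 2, 5, 2, 6, 5,   # b = -
        3, 7, 4, 4, 7, 8,   # b = +
        1, 5, 3, 3, 5, 7,   # c = -
        2, 4, 6, 4, 8, 6),  # c = +
        ncol = 3, byrow = TRUE)
      F <- rbind(F, Fb, vc + cube_tris)
      marker_flag <- c(marker_flag,
                       rep(TRUE, 16 + 8))
      centers <- rbind(centers, ctr)
    }
  }
  mesh <- limb_mesh(V, F, marker_vertex = marker_flag)
  attr(mesh, "marker_centers") <- centers
  attr(mesh, "seed") <- seed
  mesh
}

#' Per-vertex temperatures for the two conditions
#'
#' Evaluates each [temperature_field()] on the mesh: base temperature plus
#' Gaussian bumps of the given peaks and radii (chordal distance to the
#' spot centre; spot radii are small against the limb radius, so the chord
#' approximates the geodesic), then overrides marker vertices with the
#' marker temperature — identical in both conditions, which is what makes
#' the markers' differential halos near zero.
#'
#' @param mesh a [make_limb_mesh()] result.
#' @param rest,post_walk [temperature_field()] objects.
#' @param spec the [limb_spec()] used for the mesh (locates spot centres).
#' @param markers the [marker_spec()] (marker temperature).
#' @param anchors skin values must stay within this range, degC (default
#'   c(28, 37), the colormap anchors).
#' @return list with numeric vectors `rest` and `post_walk` (degC per
#'   vertex).
#' @export
make_temperature_fields <- function(mesh, rest, post_walk,
                                    spec = limb_spec(),
                                    markers = marker_spec(),
                                    anchors = c(28, 37)) {
  evalf <- function(field) {
    t <- rep(field$base_temperature, nrow(mesh$vertices))
    sp <- field$spots
    if (nrow(sp) > 0)
      for (i in seq_len(nrow(sp))) {
        ctr <- limb_surface_point(spec, sp$axial[i], sp$azimuth_deg[i])
        d2 <- rowSums(sweep(mesh$vertices, 2, ctr)^2)
        t <- t + sp$peak[i] * exp(-d2 / (2 * sp$radius[i]^2))
      }
    skin <- !mesh$marker_vertex
    if (any(t[skin] < anchors[1] | t[skin] > anchors[2]))
      stop(sprintf(
        "composed skin temperatures [%.2f, %.2f] degC outside [%g, %g]",
        min(t[skin]), max(t[skin]), anchors[1], anchors[2]), call. = FALSE)
    t[mesh$marker_vertex] <- markers$marker_temperature
    t
  }
  list(rest = evalf(rest), post_walk = evalf(post_walk))
}

#' Default acquisition conditions of the synthetic scene
#'
#' The two skin-temperature fields the generator emulates, following the
#' clinical picture of a transtibial stump: a resting skin of 31 degC
#' with distal cooling (the distal end is the coolest region) and three
#' residual warm areas, and a post-walk skin uniformly ~1.4 degC warmer
#' whose warm areas (suprapatellar-, flap- and popliteal-like locations)
#' intensify towards 36 degC. The post-walk minus rest difference is
#' >= 1.2 degC on every skin vertex while marker vertices stay
#' identical — which is what makes the marker halos detectable in the
#' differential map.
#'
#' @return list with `rest` and `post_walk` [temperature_field()]s.
#' @export
default_condition_fields <- function() {
  spots <- function(distal, supra, flap, popliteal)
    data.frame(axial = c(0, 0.85, 0.55, 0.80),
               azimuth_deg = c(0, 10, 150, 200),
               peak = c(distal, supra, flap, popliteal),
               radius = c(0.05, 0.025, 0.020, 0.030))
  list(
    rest = temperature_field(31.0, spots(-1.3, 2.2, 1.6, 1.9),
                             condition_label = "rest"),
    post_walk = temperature_field(32.4, spots(-1.1, 3.4, 2.6, 3.0),
                                  condition_label = "post_walk"))
}

#' Camera poses of the rotating-platform acquisition
#'
#' Places the camera at the acquisition distance from the limb axis,
#' level with the limb mid-height, at azimuths starting frontal and
#' stepping by 45 degrees — the at-least-7-views protocol.
#'
#' @param n_views number of views (default 7).
#' @param start_deg,step_deg azimuth start/step, degrees (defaults 0, 45).
#' @param distance camera-to-axis distance, m (default 1.20).
#' @param aim_height height of the aimed point on the axis, m (default
#'   half the default limb length).
#' @return list of [view_pose()]s, named by azimuth.
#' @export
platform_view_poses <- function(n_views = 7L, start_deg = 0,
                                step_deg = 45, distance = 1.20,
                                aim_height = 0.10) {
  az <- start_deg + step_deg * (seq_len(n_views) - 1L)
  poses <- lapply(az, function(a)
    look_at_pose(c(distance * cos(a * pi / 180),
                   distance * sin(a * pi / 180), aim_height),
                 c(0, 0, aim_height)))
  names(poses) <- sprintf("az%03d", as.integer(az %% 360))
  poses
}

#' Pose of a camera at `eye` looking at `target` (world z up, image y
#' down)
#' @param eye,target world points, metres.
#' @return a [view_pose()].
#' @export
look_at_pose <- function(eye, target) {
  zc <- target - eye
  zc <- zc / sqrt(sum(zc^2))
  up <- c(0, 0, 1)
  yc <- -(up - sum(up * zc) * zc)
  if (sqrt(sum(yc^2)) < 1e-9) yc <- c(0, -1, 0)  # looking straight down
  yc <- yc / sqrt(sum(yc^2))
  xc <- pracma_cross(yc, zc)
  R <- rbind(xc, yc, zc)
  view_pose(R, -drop(R %*% eye))
}

#' Render a thermal frame of the scene
#'
#' Projects the mesh through the distorted camera model and rasterises the
#' per-vertex temperatures with a z-buffer (perspective-correct
#' barycentric interpolation). Background pixels take the ambient
#' temperature; optional additive Gaussian sensor noise at the camera's
#' NETD.
#'
#' @param mesh a [limb_mesh()].
#' @param temperatures per-vertex temperatures, degC.
#' @param camera a [camera_model()].
#' @param pose a [view_pose()].
#' @param noise_sd sensor noise sd, degC (default 0.07, the NETD; use 0
#'   for noiseless renders).
#' @param ambient background temperature, degC (default 23).
#' @param view_id frame label.
#' @return a [thermal_frame()].
#' @export
render_thermal_frame <- function(mesh, temperatures, camera, pose,
                                 noise_sd = 0.07, ambient = 23,
                                 view_id = "synthetic") {
  r <- render_attribute(mesh, temperatures, camera, pose,
                        background = ambient)
  if (all(r$face == 0L))
    stop("mesh renders outside the camera frustum (empty image)",
         call. = FALSE)
  vals <- r$image
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow(vals))
  thermal_frame(vals, view_id = view_id,
                metadata = acquisition_metadata())
}

# Rasterize an arbitrary per-vertex attribute; returns image, depth, face
# buffers (rows = image rows, top first).
render_attribute <- function(mesh, values, camera, pose, background = 0) {
  uv <- project_points(camera, pose, mesh$vertices, allow_behind = TRUE)
  depth <- attr(uv, "depth")
  uv[is.na(uv)] <- -1e9
  rasterize_mesh_cpp(uv, depth, mesh$faces, values,
                     camera$width, camera$height, background)
}

# Lambertian shading of the mesh seen from a pose: cos of the angle
# between the vertex normal and the direction to the camera, clamped >= 0.
shading_values <- function(mesh, pose) {
  cam_pos <- -drop(t(pose$rotation) %*% pose$translation)
  d <- sweep(-mesh$vertices, 2, cam_pos, "+")   # vertex -> camera
  d <- d / pmax(sqrt(rowSums(d^2)), 1e-12)
  pmax(rowSums(mesh$normals * d), 0)
}

#' Generate the full synthetic scene
#'
#' Builds the limb mesh with fiducials, evaluates the rest and post-walk
#' temperature fields, and renders the 7-view thermal frames for each
#' condition through the thermal camera at the platform geometry, with
#' sensor noise. This is the ground-truth dataset every downstream stage
#' is validated against.
#'
#' @param seed integer seed; geometry uses `seed`, sensor noise
#'   `seed + 1`.
#' @param spec,markers,camera scene specifications (study-condition
#'   defaults).
#' @param fields rest/post-walk fields (default
#'   [default_condition_fields()]).
#' @param n_views views per condition (default 7).
#' @param noise_sd sensor noise, degC (default 0.07).
#' @return list: `mesh`, `temperatures` (list rest/post_walk),
#'   `marker_centers`, `poses`, `camera`, `frames` (list of lists of
#'   [thermal_frame()]s), `seed`.
#' @export
simulate_scene <- function(seed = 1L, spec = limb_spec(),
                           markers = marker_spec(),
                           camera = camera_model(),
                           fields = default_condition_fields(),
                           n_views = 7L, noise_sd = 0.07) {
  mesh <- make_limb_mesh(spec, markers, seed = seed)
  temps <- make_temperature_fields(mesh, fields$rest, fields$post_walk,
                                   spec = spec, markers = markers)
  poses <- platform_view_poses(n_views = n_views,
                               aim_height = spec$length / 2)
  set.seed(seed + 1L)
  frames <- lapply(c(rest = "rest", post_walk = "post_walk"),
                   function(cond)
    lapply(seq_along(poses), function(i)
      render_thermal_frame(mesh, temps[[cond]], camera, poses[[i]],
                           noise_sd = noise_sd,
                           view_id = sprintf("%s_%s", cond,
                                             names(poses)[i]))))
  list(mesh = mesh, temperatures = temps,
       marker_centers = attr(mesh, "marker_centers"),
       poses = poses, camera = camera, frames = frames, seed = seed)
}
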