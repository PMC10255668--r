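test_that("limb mesh hits the resolution target and records marker centres", {
  sc <- small_scene()
  mesh <- sc$mesh
  expect_lt(abs(nrow(mesh$vertices) - 4000) / 4000, 0.2)
  expect_equal(nrow(sc$marker_centers), 5L)
  # cube centre sits at radius(z) + base_thickness + edge/2 from the axis
  spec <- limb_spec(mesh_resolution = 4000L)
  mk <- marker_spec()
  ctr <- sc$marker_centers[1, ]
  z <- mk$placements$axial[1] * spec$length
  expected_rho <- thermomap3d:::limb_radius_at(spec, z) +
    (mk$base_thickness_mm + mk$cube_edge_mm / 2) / 1000
  expect_equal(sqrt(sum(ctr[1:2]^2)), expected_rho, tolerance = 1e-9)
  expect_equal(ctr[3], z)
  # determinism: same seed, identical mesh
  m2 <- make_limb_mesh(spec, mk, seed = 1L)
  expect_identical(m2$vertices, mesh$vertices)
  expect_identical(m2$faces, mesh$faces)
  # overlapping placements are rejected
  expect_error(make_limb_mesh(spec, marker_spec(placements = data.frame(
    axial = c(0.5, 0.5), azimuth_deg = c(0, 1))), seed = 1),
    "overlapping")
})

test_that("temperature fields compose base, spots and marker override", {
  spec <- limb_spec(mesh_resolution = 4000L)
  mesh <- make_limb_mesh(spec, seed = 1L)
  flat <- temperature_field(31)
  spot <- temperature_field(31, data.frame(axial = 0.5, azimuth_deg = 0,
                                           peak = 5, radius = 0.02))
  tf <- make_temperature_fields(mesh, flat, spot, spec = spec)
  skin <- !mesh$marker_vertex
  expect_true(all(tf$rest[skin] == 31))
  # peak arithmetic: temperature at the spot centre reaches base + peak
  ctr <- thermomap3d:::limb_surface_point(spec, 0.5, 0)
  i <- which.min(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  expect_equal(tf$post_walk[i], 36, tolerance = 0.3)
  # markers identical across conditions -> differential exactly zero
  expect_true(all(tf$post_walk[mesh$marker_vertex] ==
                    tf$rest[mesh$marker_vertex]))
  expect_true(all(tf$rest[mesh$marker_vertex] == 26))
  # out-of-range compositions are rejected, not clipped
  too_hot <- temperature_field(31, data.frame(axial = 0.5, azimuth_deg = 0,
                                              peak = 8, radius = 0.02))
  expect_error(make_temperature_fields(mesh, flat, too_hot, spec = spec),
               "outside")
})

test_that("platform poses step by 45 degrees at 1.2 m from the axis", {
  poses <- platform_view_poses()
  expect_length(poses, 7L)
  pos <- t(vapply(poses, function(p)
    -drop(t(p$rotation) %*% p$translation), numeric(3)))
  # camera distance from the limb axis
  expect_equal(sqrt(rowSums(pos[, 1:2]^2)), rep(1.2, 7),
               tolerance = 1e-12, ignore_attr = TRUE)
  az <- atan2(pos[, 2], pos[, 1]) * 180 / pi
  expect_equal(unname(diff(az %% 360)), rep(45, 6), tolerance = 1e-9)
})

test_that("noiseless renders show surface temperature and ambient background", {
  sc <- small_scene()
  spec <- limb_spec(mesh_resolution = 4000L)
  mesh <- make_limb_mesh(spec, seed = 1L)
  temps <- rep(31, nrow(mesh$vertices))
  fr <- render_thermal_frame(mesh, temps, sc$camera, sc$poses[[1]],
                             noise_sd = 0, view_id = "t")
  vals <- fr$values
  # constant limb, ambient background (interpolation of a constant can
  # leave float residue)
  expect_true(all(abs(vals - 23) < 1e-9 | abs(vals - 31) < 1e-9))
  expect_gt(sum(abs(vals - 31) < 1e-9), 3000)
  expect_gt(sum(abs(vals - 23) < 1e-9), 50000)
  # sensor noise is additive with the requested sd
  fr2 <- render_thermal_frame(mesh, temps, sc$camera, sc$poses[[1]],
                              noise_sd = 0.07, view_id = "t")
  bg <- fr2$values[vals == 23]
  expect_equal(sd(bg), 0.07, tolerance = 0.01)
  # a pose looking away from the mesh is an error
  away <- view_pose(diag(3), c(0, 0, -5))
  expect_error(render_thermal_frame(mesh, temps, sc$camera, away,
                                    noise_sd = 0),
               "outside the camera frustum")
})

test_that("renderer agrees with an independent ray-cast oracle", {
  sc <- small_scene()
  mesh <- sc$mesh
  temps <- sc$temperatures$rest
  pose <- sc$poses[[2]]
  r <- thermomap3d:::render_attribute(mesh, temps, sc$camera, pose,
                                      background = NA)
  cam_pos <- -drop(t(pose$rotation) %*% pose$translation)
  set.seed(9)
  lit <- which(r$face > 0, arr.ind = TRUE)
  pick <- lit[sample(nrow(lit), 100), ]
  Vc <- mesh$vertices %*% t(pose$rotation) +
    matrix(pose$translation, nrow(mesh$vertices), 3, byrow = TRUE)
  n_checked <- 0
  for (k in seq_len(nrow(pick))) {
    u <- pick[k, 2] - 1; v <- pick[k, 1] - 1
    ray_c <- drop(pixel_rays(sc$camera, c(u, v)))
    ray_w <- drop(t(pose$rotation) %*% ray_c)
    hit <- ray_mesh_intersect_cpp(matrix(cam_pos, 1), matrix(ray_w, 1),
                                  mesh$vertices, mesh$faces)
    if (hit$face[1] == 0) next
    f <- mesh$faces[hit$face[1], ]
    b <- c(1 - sum(hit$bary[1, ]), hit$bary[1, ])
    t_hit <- sum(b * temps[f])
    # skip pixels on depth discontinuities where the rasterised triangle
    # and the exact ray hit legitimately differ
    zpix <- r$depth[pick[k, 1], pick[k, 2]]
    if (abs(hit$t[1] - zpix / ray_c[3]) > 0.005) next
    expect_equal(r$image[pick[k, 1], pick[k, 2]], t_hit,
                 tolerance = 0.15)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 70)
})

test_that("scene serialisation produces a readable dataset", {
  sc <- small_scene(noise_sd = 0.07)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(file.exists(file.path(dir, "limb_synthetic.ply")))
  expect_true(file.exists(file.path(dir, "camera.json")))
  csvs <- list.files(dir, pattern = "\\.csv$")
  expect_length(csvs, 14L)   # 7 views x 2 conditions
  fr <- read_thermal_frame(file.path(dir, csvs[1]))
  expect_s3_class(fr, "thermal_frame")
  mesh <- read_ply(file.path(dir, "limb_synthetic.ply"))
  expect_equal(nrow(mesh$vertices), nrow(sc$mesh$vertices))
  expect_true(!is.null(mesh$scalars$t_rest))
})
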