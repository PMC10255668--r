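make_temp_mesh <- function(base_mesh, temps) {
  base_mesh$vertex_temperature <- temps
  base_mesh
}

test_that("differential map subtracts per vertex and is antisymmetric", {
  sc <- small_scene()
  n <- nrow(sc$mesh$vertices)
  a <- make_temp_mesh(sc$mesh, sc$temperatures$post_walk)
  b <- make_temp_mesh(sc$mesh, sc$temperatures$rest)
  d <- differential_map(a, b)
  skin <- !sc$mesh$marker_vertex
  expect_equal(d$delta_t,
               sc$temperatures$post_walk - sc$temperatures$rest)
  expect_true(all(d$delta_t[!skin] == 0))   # markers unchanged
  # antisymmetry is exact
  d2 <- differential_map(b, a)
  expect_identical(d$delta_t, -d2$delta_t)
  # colour coding spans first..last jet row over the observed range
  imin <- which.min(d$delta_t); imax <- which.max(d$delta_t)
  expect_equal(d$rgb[imin, ], unname(jet_rgb(0)[1, ]))
  expect_equal(d$rgb[imax, ], unname(jet_rgb(1)[1, ]))
  # marker vertices sit at the minimum (zero) difference: deep blue
  expect_true(all(d$rgb[!skin, 3] == 128L & d$rgb[!skin, 1] == 0L))
  # NA propagates
  a$vertex_temperature[5] <- NA
  expect_true(is.na(differential_map(a, b)$delta_t[5]))
  # mismatched meshes are rejected
  short <- make_temp_mesh(
    limb_mesh(sc$mesh$vertices[1:10, ],
              matrix(c(1L, 2L, 3L), 1)), rep(30, 10))
  expect_error(differential_map(a, short), "mismatch")
})

test_that("halo statistics match a sorting oracle on controlled distances", {
  # one isolated halo vertex per marker at a controlled distance
  dists_mm <- c(0.0, 1.0, 2.7, 2.7, 3.5, 4.0, 5.0)
  k <- length(dists_mm)
  centers <- cbind(seq_len(k) * 0.1, 0, 0)
  verts <- centers + cbind(0, dists_mm / 1000, 0)
  mesh <- limb_mesh(verts, matrix(c(1L, 2L, 3L), 1))
  a <- make_temp_mesh(mesh, rep(31, k)); b <- make_temp_mesh(mesh, rep(31, k))
  d <- differential_map(a, b)
  st <- marker_halo_error(d, centers, search_radius = 0.006,
                          zero_tolerance = 0.3)
  expect_equal(st$per_marker$distance_mm, dists_mm, tolerance = 1e-9)
  # order-statistics oracle
  s <- sort(dists_mm)
  expect_equal(st$median_mm, s[(k + 1) / 2])
  expect_equal(st$median_mm, 2.7)
  expect_equal(c(st$min_mm, st$max_mm), c(0, 5))
  expect_equal(st$sd_mm, sd(dists_mm))
  # markers with no halo are excluded and counted
  st2 <- marker_halo_error(d, rbind(centers, c(99, 99, 99)),
                           search_radius = 0.006)
  expect_equal(st2$n_missing, 1L)
  expect_equal(st2$median_mm, 2.7)
})

test_that("halo statistics are invariant under rigid scene transforms", {
  sc <- small_scene()
  a <- make_temp_mesh(sc$mesh, sc$temperatures$post_walk)
  b <- make_temp_mesh(sc$mesh, sc$temperatures$rest)
  st1 <- marker_halo_error(differential_map(a, b), sc$marker_centers)
  Q <- axis_angle_to_rotation(c(0.4, 0.2, -0.3)); tv <- c(1, -2, 0.5)
  move <- function(m) {
    m$vertices <- m$vertices %*% t(Q) +
      matrix(tv, nrow(m$vertices), 3, byrow = TRUE)
    m
  }
  st2 <- marker_halo_error(
    differential_map(move(a), move(b)),
    sc$marker_centers %*% t(Q) + matrix(tv, 5, 3, byrow = TRUE))
  expect_equal(st2$per_marker$distance_mm, st1$per_marker$distance_mm,
               tolerance = 1e-9)
  expect_equal(st2$median_mm, st1$median_mm, tolerance = 1e-9)
})

test_that("hotspot summary finds the right components by flood fill", {
  sc <- small_scene()
  mesh <- sc$mesh
  # constant field below threshold: nothing
  cold <- make_temp_mesh(mesh, rep(30, nrow(mesh$vertices)))
  expect_equal(nrow(summarize_hotspots(cold, 34)), 0L)
  # one Gaussian spot peaking at 36: exactly one component with the peak
  spec <- limb_spec(mesh_resolution = 4000L)
  f <- make_temperature_fields(
    mesh, temperature_field(31),
    temperature_field(31, data.frame(axial = 0.5, azimuth_deg = 90,
                                     peak = 5, radius = 0.02)),
    spec = spec)
  warm <- make_temp_mesh(mesh, f$post_walk)
  hs <- summarize_hotspots(warm, 34)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$peak_c, max(f$post_walk), tolerance = 1e-9)
  expect_gt(hs$area_m2, 0)
  # two disjoint spots -> two components, matching an igraph flood fill
  f2 <- make_temperature_fields(
    mesh, temperature_field(31),
    temperature_field(31, data.frame(axial = c(0.2, 0.8),
                                     azimuth_deg = c(0, 180),
                                     peak = c(5, 5),
                                     radius = c(0.015, 0.015))),
    spec = spec)
  hs2 <- summarize_hotspots(make_temp_mesh(mesh, f2$post_walk), 34)
  expect_equal(nrow(hs2), 2L)
})

test_that("differential PLY and stats JSON serialise round-trip", {
  sc <- small_scene()
  a <- make_temp_mesh(sc$mesh, sc$temperatures$post_walk)
  b <- make_temp_mesh(sc$mesh, sc$temperatures$rest)
  d <- differential_map(a, b)
  st <- marker_halo_error(d, sc$marker_centers)
  dir <- withr::local_tempdir()
  write_differential_ply(d, file.path(dir, "diff.ply"))
  back <- read_ply(file.path(dir, "diff.ply"))
  expect_equal(back$scalars$delta_t, unname(d$delta_t), tolerance = 1e-5)
  write_error_stats(st, file.path(dir, "stats.json"))
  j <- jsonlite::read_json(file.path(dir, "stats.json"),
                           simplifyVector = TRUE)
  expect_equal(j$median_mm, st$median_mm, tolerance = 1e-9)
  expect_equal(nrow(j$per_marker), 5L)
})
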