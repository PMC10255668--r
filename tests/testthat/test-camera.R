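test_that("projection matches a step-by-step pinhole+distortion oracle", {
  cam <- camera_model()
  # on-axis point through the identity pose lands on the principal point
  uv <- project_points(cam, view_pose(diag(3), c(0, 0, 0)), c(0, 0, 1.2))
  expect_equal(unname(uv[1, ]), c(274.4383, 145.2130), tolerance = 1e-9)
  # r = 0 offset: distortion factor exactly 1
  uv0 <- project_points(cam, view_pose(diag(3), c(0, 0, 1.2)), c(0, 0, 0.3))
  expect_equal(unname(uv0[1, ]), c(cam$cx, cam$cy), tolerance = 1e-12)

  set.seed(11)
  pose <- view_pose(axis_angle_to_rotation(c(0.1, -0.2, 0.05)),
                    c(0.02, -0.03, 1.1))
  for (i in 1:20) {
    p <- c(runif(2, -0.1, 0.1), runif(1, -0.1, 0.1))
    pc <- drop(pose$rotation %*% p) + pose$translation
    xn <- pc[1] / pc[3]; yn <- pc[2] / pc[3]
    r2 <- xn^2 + yn^2
    f <- 1 + cam$k1 * r2 + cam$k2 * r2^2
    oracle <- c(cam$fx * xn * f + cam$cx, cam$fy * yn * f + cam$cy)
    uv <- project_points(cam, pose, p)
    expect_equal(unname(uv[1, ]), oracle, tolerance = 1e-9)
  }
  expect_error(project_points(cam, view_pose(diag(3), c(0, 0, 0)),
                              c(0, 0, -1)), "behind")
})

test_that("undistortion inverts the radial model for moderate radii", {
  cam <- camera_model()
  set.seed(4)
  # normalised radii up to 0.45: undistorted pixel matches the ideal
  # pinhole projection to 1e-6 px
  xn <- runif(50, -0.32, 0.32); yn <- runif(50, -0.32, 0.32)
  ideal <- cbind(cam$fx * xn + cam$cx, cam$fy * yn + cam$cy)
  r2 <- xn^2 + yn^2
  f <- 1 + cam$k1 * r2 + cam$k2 * r2^2
  distorted <- cbind(cam$fx * xn * f + cam$cx, cam$fy * yn * f + cam$cy)
  und <- undistort_points(cam, distorted)
  expect_lt(max(abs(und - ideal)), 1e-6)
})

test_that("pose constructors reject invalid rotations", {
  expect_error(view_pose(diag(3) * 1.001, c(0, 0, 0)), "orthonormal")
  expect_error(view_pose(diag(c(1, 1, -1)), c(0, 0, 0)), "determinant")
  # Rodrigues round trip
  set.seed(2)
  for (i in 1:10) {
    v <- runif(3, -1, 1) * runif(1, 0.01, 3)
    R <- axis_angle_to_rotation(v)
    expect_equal(axis_angle_to_rotation(rotation_to_axis_angle(R)), R,
                 tolerance = 1e-9)
    q <- rotation_to_quaternion(R)
    expect_equal(quaternion_to_rotation(q), R, tolerance = 1e-9)
  }
})

test_that("corner grid derives the inner-corner lattice from the board", {
  g <- corner_grid(30, c(300, 180))
  expect_equal(attr(g, "n_cols"), 9L)   # 300/30 squares -> 9 inner
  expect_equal(attr(g, "n_rows"), 5L)   # 180/30 squares -> 5 inner
  expect_equal(nrow(g), 45L)
  expect_equal(g[1, ], c(0.030, 0.030, 0))  # first corner at (30, 30) mm
  expect_true(all(g[, 3] == 0))
  expect_error(corner_grid(300, c(300, 300)), "no inner corners")
})

test_that("calibration recovers a known camera exactly from noiseless views", {
  truth <- camera_model()
  views <- make_calibration_views(truth, n_views = 20, noise_sd = 0,
                                  seed = 7)
  cal <- calibrate_camera(views)
  expect_lt(cal$mean_reprojection_error, 1e-6)
  rel <- abs(c(cal$camera$fx, cal$camera$fy, cal$camera$cx,
               cal$camera$cy) /
               c(truth$fx, truth$fy, truth$cx, truth$cy) - 1)
  expect_lt(max(rel), 1e-3)
  expect_equal(cal$camera$k1, truth$k1, tolerance = 1e-6)
  expect_equal(cal$camera$k2, truth$k2, tolerance = 1e-5)
  expect_true(cal$accepted)
  expect_error(calibrate_camera(views[1:2]), "at least 3 views")
})

test_that("correspondence CSVs round-trip through the readers", {
  truth <- camera_model()
  views <- make_calibration_views(truth, n_views = 3, noise_sd = 0,
                                  seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correspondences(views, path)
  back <- read_correspondences(path)
  expect_length(back, 3L)
  expect_equal(back[[1]]$object, unname(views[[1]]$object[, 1:3]),
               ignore_attr = TRUE)
  expect_equal(back[[1]]$image, views[[1]]$image, ignore_attr = TRUE)
})

test_that("camera JSON serialisation mirrors the calibration fields", {
  cam <- camera_model(fx = 700, fy = 710, cx = 160, cy = 120,
                      k1 = -0.2, k2 = -0.9)
  path <- withr::local_tempfile(fileext = ".json")
  write_camera_model(cam, path)
  back <- read_camera_model(path)
  expect_equal(back, cam)
})
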