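test_that("marker blobs are detected within a pixel of their projections", {
  sc <- small_scene(noise_sd = 0.07)
  found <- 0L
  for (i in seq_along(sc$poses)) {
    fr <- sc$frames$rest[[i]]
    blobs <- detect_marker_blobs(fr)
    pred <- project_points(sc$camera, sc$poses[[i]], sc$marker_centers,
                           allow_behind = TRUE)
    cam_pos <- -drop(t(sc$poses[[i]]$rotation) %*%
                       sc$poses[[i]]$translation)
    outward <- cbind(sc$marker_centers[, 1], sc$marker_centers[, 2], 0)
    outward <- outward / sqrt(rowSums(outward^2))
    facing <- rowSums((matrix(cam_pos, 5, 3, byrow = TRUE) -
                         sc$marker_centers) * outward) > 0.3
    for (m in which(facing)) {
      d <- sqrt((blobs$u - pred[m, 1])^2 + (blobs$v - pred[m, 2])^2)
      expect_lt(min(d), 1.6)
      found <- found + 1L
    }
  }
  expect_gte(found, 10L)
  # constant frame: nothing to detect
  none <- detect_marker_blobs(thermal_frame(matrix(30, 240, 320)))
  expect_equal(nrow(none), 0L)
})

test_that("noiseless PnP recovers the exact pose", {
  cam <- camera_model()
  set.seed(21)
  for (i in 1:5) {
    P <- matrix(rnorm(12, sd = 0.05), 4, 3)
    pose <- look_at_pose(c(1.2 * cos(i), 1.2 * sin(i), 0.1), c(0, 0, 0))
    uv <- project_points(cam, pose, P)
    fit <- estimate_pose_from_fiducials(list(image = uv, object = P), cam)
    expect_lt(rotation_angle_deg(fit$pose$rotation, pose$rotation), 0.01)
    expect_lt(1000 * sqrt(sum((fit$pose$translation -
                                 pose$translation)^2)), 0.1)
  }
})

test_that("PnP degrades gracefully under centroid noise (Monte-Carlo)", {
  cam <- camera_model()
  errs <- matrix(0, 100, 2)
  set.seed(31)
  pose <- look_at_pose(c(1.2, 0, 0.1), c(0, 0, 0.1))
  # 4 markers spread like the fiducials on the limb
  P <- cbind(runif(4, -0.05, 0.05), runif(4, -0.05, 0.05),
             runif(4, 0, 0.2))
  for (s in 1:100) {
    uv <- project_points(cam, pose, P) +
      matrix(rnorm(8, 0, 1), 4, 2)
    fit <- estimate_pose_from_fiducials(list(image = uv, object = P),
                                        cam, init = pose)
    d <- fit$pose$translation - pose$translation
    # translation is expressed in the camera frame: components 1:2 are
    # in-image-plane, component 3 is depth along the optical axis
    errs[s, ] <- 1000 * c(sqrt(sum(d^2)), sqrt(sum(d[1:2]^2)))
  }
  # in-plane translation is recovered to a few mm; depth is weakly
  # observable from a 10-20 cm marker spread seen at 120 cm and
  # dominates the full error
  expect_lt(median(errs[, 2]), 5)
  expect_lt(median(errs[, 1]), 25)
})

test_that("collinear markers raise a degenerate-configuration error", {
  cam <- camera_model()
  P <- cbind(0.01 * (1:3), 0.02 * (1:3), 0.05 * (1:3))
  uv <- matrix(c(100, 100, 110, 120, 120, 140), 3, 2)
  expect_error(estimate_pose_from_fiducials(list(image = uv, object = P),
                                            cam), "collinear")
  expect_error(estimate_pose_from_fiducials(
    list(image = uv[1:2, ], object = P[1:2, ]), cam), "at least 3")
})

test_that("PnP is equivariant under rigid transforms of the scene", {
  cam <- camera_model()
  set.seed(8)
  P <- matrix(rnorm(15, sd = 0.04), 5, 3)
  pose <- look_at_pose(c(1.1, 0.2, 0.05), c(0, 0, 0))
  uv <- project_points(cam, pose, P)
  fit1 <- estimate_pose_from_fiducials(list(image = uv, object = P), cam)
  # rigidly move the world: x' = Q x + d
  Q <- axis_angle_to_rotation(c(0.3, -0.1, 0.4)); d <- c(0.2, -0.1, 0.05)
  P2 <- P %*% t(Q) + matrix(d, 5, 3, byrow = TRUE)
  fit2 <- estimate_pose_from_fiducials(list(image = uv, object = P2), cam)
  # the recovered pose must compose: R2 = R1 Q', t2 = t1 - R1 Q' d
  expect_equal(fit2$pose$rotation, fit1$pose$rotation %*% t(Q),
               tolerance = 1e-6)
  expect_equal(fit2$pose$translation,
               fit1$pose$translation -
                 drop(fit1$pose$rotation %*% t(Q) %*% d),
               tolerance = 1e-6)
})

test_that("mutual information has its analytic fixed points", {
  set.seed(5)
  # MI(X, X) equals H(X): 32 equally likely discrete values
  x <- matrix(rep(seq_len(32), length.out = 128 * 128), 128)
  x <- x[sample(length(x))]; dim(x) <- c(128, 128)
  expect_equal(mutual_information(x, x), log2(32), tolerance = 1e-9)
  # symmetry and non-negativity
  y <- matrix(runif(128 * 128), 128)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_gte(mutual_information(x, y), 0)
  # independent noise: MI stays at the finite-sample bias level,
  # bounded by (B-1)^2/(2 N ln 2) bits
  n <- 100 * 100
  a <- matrix(runif(n), 100); b <- matrix(runif(n), 100)
  bias_bound <- 31^2 / (2 * n * log(2))
  expect_lt(mutual_information(a, b), 1.25 * bias_bound)
  # invariance under a bin-preserving monotone transform (affine)
  expect_equal(mutual_information(x, 3 * y + 7),
               mutual_information(x, y), tolerance = 1e-12)
  expect_error(mutual_information(x, y, mask = matrix(FALSE, 128, 128)),
               "empty mask")
})

test_that("MI refinement does not worsen a ground-truth pose", {
  sc <- small_scene(noise_sd = 0.07)
  fr <- sc$frames$rest[[2]]
  res <- refine_pose(sc$poses[[2]], fr, sc$mesh, sc$camera, maxit = 60)
  expect_gte(res$mi_score, res$mi_initial)
  expect_lt(1000 * sqrt(sum((res$pose$translation -
                               sc$poses[[2]]$translation)^2)), 5)
  expect_lt(rotation_angle_deg(res$pose$rotation,
                               sc$poses[[2]]$rotation), 1)
})

test_that("MI refinement recovers a perturbed pose on a noiseless render", {
  sc <- small_scene()
  fr <- render_thermal_frame(sc$mesh, sc$temperatures$rest, sc$camera,
                             sc$poses[[3]], noise_sd = 0, view_id = "x")
  truth <- sc$poses[[3]]
  pert <- thermomap3d:::perturb_pose(truth,
                                     c(0.02, -0.015, 0.02,
                                       0.003, -0.004, 0.002))
  proj_rmse <- function(pose) {
    a <- project_points(sc$camera, pose, sc$marker_centers,
                        allow_behind = TRUE)
    b <- project_points(sc$camera, truth, sc$marker_centers,
                        allow_behind = TRUE)
    sqrt(mean(rowSums((a - b)^2), na.rm = TRUE))
  }
  res <- refine_pose(pert, fr, sc$mesh, sc$camera, maxit = 200)
  expect_lt(proj_rmse(res$pose), proj_rmse(pert))
  expect_gt(res$mi_score, res$mi_initial)
})

test_that("register_view initialises from fiducials and reports usage", {
  sc <- small_scene(noise_sd = 0.07)
  res <- register_view(sc$frames$rest[[1]], sc$mesh, sc$marker_centers,
                       sc$camera, sc$poses[[1]], refine = FALSE)
  expect_s3_class(res, "registration_result")
  expect_gte(res$n_markers_used, 2L)
  if (res$n_markers_used >= 3L) expect_lt(res$fiducial_rmse, 2)
  # pose close to the nominal truth
  expect_lt(1000 * sqrt(sum((res$pose$translation -
                               sc$poses[[1]]$translation)^2)), 30)
})
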