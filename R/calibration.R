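#' Planar-target camera calibration
#'
#' Calibrates the thermal camera from views of a planar chessboard grid:
#' per-view homographies (normalised DLT) give a closed-form initial
#' estimate of the intrinsics (absolute-conic constraints) and per-view
#' extrinsics; a joint Levenberg-Marquardt refinement over intrinsics,
#' two radial distortion terms and all poses then minimises the total
#' reprojection error. Calibration is accepted when the mean reprojection
#' error is below 1 pixel.
#'
#' @param views list of views, each a list with `object` (n x 3 planar
#'   points, z = 0, metres) and `image` (n x 2 observed pixels); at least 3
#'   views of a non-degenerate planar grid.
#' @param image_size image (width, height) in pixels, default c(320, 240).
#' @param fix_skew keep the skew at 0 during refinement (default TRUE).
#' @param max_iter LM iteration cap (default 200).
#' @return An object of class `calibration_result`: `camera`
#'   ([camera_model()]), `poses` (list of [view_pose()]),
#'   `mean_reprojection_error` (pixels, mean Euclidean distance over all
#'   corners), `accepted` (`TRUE` iff below 1 px), `per_view_error`.
#' @export
calibrate_camera <- function(views, image_size = c(320L, 240L),
                             fix_skew = TRUE, max_iter = 200L) {
  if (length(views) < 3L)
    stop(sprintf(
      "calibration needs at least 3 views (got %d): planar self-calibration is rank-deficient",
      length(views)), call. = FALSE)
  H <- lapply(views, function(v)
    homography_dlt(v$object[, 1:2, drop = FALSE], v$image))
  K0 <- intrinsics_from_homographies(H)
  if (fix_skew) K0[1, 2] <- 0
  poses0 <- lapply(H, function(h) extrinsics_from_homography(K0, h))

  pack <- function(cam_par, poses) {
    c(cam_par, unlist(lapply(poses, function(p)
      c(rotation_to_axis_angle(p$rotation), p$translation))))
  }
  unpack <- function(par) {
    cam <- camera_model(fx = par[1], fy = par[2], cx = par[3], cy = par[4],
                        k1 = par[5], k2 = par[6],
                        skew = if (fix_skew) 0 else par[7],
                        width = image_size[1], height = image_size[2])
    off <- if (fix_skew) 6L else 7L
    poses <- lapply(seq_along(views), function(i) {
      p <- par[off + (i - 1) * 6 + 1:6]
      view_pose(axis_angle_to_rotation(p[1:3]), p[4:6])
    })
    list(cam = cam, poses = poses)
  }
  resid_fn <- function(par) {
    st <- unpack(par)
    unlist(lapply(seq_along(views), function(i) {
      uv <- project_points(st$cam, st$poses[[i]], views[[i]]$object,
                           allow_behind = TRUE)
      r <- uv - views[[i]]$image
      r[is.na(r)] <- 1e3  # corners driven behind the camera are penalised
      as.vector(r)
    }))
  }

  par0 <- c(K0[1, 1], K0[2, 2], K0[1, 3], K0[2, 3], 0, 0,
            if (!fix_skew) K0[1, 2])
  par0 <- pack(par0, poses0)
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-12, ptol = 1e-12))
  st <- unpack(fit$par)

  per_corner <- lapply(seq_along(views), function(i) {
    uv <- project_points(st$cam, st$poses[[i]], views[[i]]$object,
                         allow_behind = TRUE)
    sqrt(rowSums((uv - views[[i]]$image)^2))
  })
  per_view <- vapply(per_corner, mean, numeric(1))
  err <- mean(unlist(per_corner))
  structure(
    list(camera = st$cam, poses = st$poses,
         mean_reprojection_error = err,
         per_view_error = per_view,
         accepted = err < 1.0,
         iterations = fit$niter),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %d views, mean reprojection error %.4f px (%s)\n",
    length(x$poses), x$mean_reprojection_error,
    if (x$accepted) "accepted: < 1 px" else "rejected: >= 1 px"))
  print(x$camera)
  invisible(x)
}

# --- closed-form initialisation ---------------------------------------------

homography_dlt <- function(xy, uv) {
  stopifnot(nrow(xy) >= 4)
  norm_t <- function(p) {
    m <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, m)^2)))
    matrix(c(s, 0, 0, 0, s, 0, -s * m[1], -s * m[2], 1), 3, 3)
  }
  T1 <- norm_t(xy); T2 <- norm_t(uv)
  ph <- cbind(xy, 1) %*% t(T1)
  qh <- cbind(uv, 1) %*% t(T2)
  n <- nrow(xy)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- ph[i, ]; u <- qh[i, 1]; v <- qh[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A)$v[, 9]
  H <- solve(T2) %*% matrix(h, 3, 3, byrow = TRUE) %*% T1
  H / H[3, 3]
}

intrinsics_from_homographies <- function(H) {
  vrow <- function(h, i, j) {
    c(h[1, i] * h[1, j],
      h[1, i] * h[2, j] + h[2, i] * h[1, j],
      h[2, i] * h[2, j],
      h[3, i] * h[1, j] + h[1, i] * h[3, j],
      h[3, i] * h[2, j] + h[2, i] * h[3, j],
      h[3, i] * h[3, j])
  }
  V <- do.call(rbind, lapply(H, function(h)
    rbind(vrow(h, 1, 2), vrow(h, 1, 1) - vrow(h, 2, 2))))
  b <- svd(V)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  v0 <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  alpha <- sqrt(abs(lam / B11))
  beta <- sqrt(abs(lam * B11 / (B11 * B22 - B12^2)))
  gamma <- -B12 * alpha^2 * beta / lam
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lam
  matrix(c(alpha, 0, 0, gamma, beta, 0, u0, v0, 1), 3, 3)
}

extrinsics_from_homography <- function(K, H) {
  M <- solve(K, H)
  lam <- 1 / sqrt(sum(M[, 1]^2))
  if (lam * M[3, 3] < 0) lam <- -lam  # board in front of the camera
  r1 <- lam * M[, 1]; r2 <- lam * M[, 2]
  R <- cbind(r1, r2, pracma_cross(r1, r2))
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  view_pose(R, lam * M[, 3])
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# --- synthetic calibration data ---------------------------------------------

#' Synthetic chessboard calibration views
#'
#' Renders ideal corner observations of a planar chessboard through a known
#' ground-truth camera: random board poses with inclination up to
#' `max_inclination_deg` relative to the image plane, all corners required
#' to land inside the image, optional Gaussian pixel noise on the corners.
#' Used to exercise the calibration math without a physical target.
#'
#' @param camera ground-truth [camera_model()].
#' @param n_views number of views (default 20).
#' @param square_mm,board_mm chessboard geometry (defaults 30 mm squares on
#'   a 300 x 180 mm board: a 9 x 5 inner-corner grid).
#' @param max_inclination_deg maximum board inclination, degrees
#'   (default 45).
#' @param noise_sd corner noise, pixels (default 0).
#' @param seed RNG seed.
#' @return list of views as consumed by [calibrate_camera()]; each has the
#'   true `pose` attached.
#' @export
make_calibration_views <- function(camera, n_views = 20L, square_mm = 30,
                                   board_mm = c(300, 180),
                                   max_inclination_deg = 45,
                                   noise_sd = 0, seed = 1L) {
  grid <- corner_grid(square_mm, board_mm)
  centre <- colMeans(grid)
  set.seed(seed)
  views <- vector("list", n_views)
  i <- 1L
  while (i <= n_views) {
    # favour strong inclinations (they carry the focal/principal-point
    # information) and spread board positions over the image
    incl <- stats::runif(1, 0.3 * max_inclination_deg,
                         max_inclination_deg) * pi / 180
    axis <- c(stats::runif(2, -1, 1), 0)
    axis <- axis / sqrt(sum(axis^2))
    roll <- stats::runif(1, -pi, pi) / 4
    R <- axis_angle_to_rotation(axis * incl) %*%
      axis_angle_to_rotation(c(0, 0, roll))
    dist <- stats::runif(1, 0.65, 1.2)
    lateral <- stats::runif(2, -0.12, 0.12) * c(1, 0.7)
    # aim the board centre near the middle of the image at the chosen
    # distance (the principal point may sit far off-centre)
    ray <- pixel_rays(camera, c((camera$width - 1) / 2,
                                (camera$height - 1) / 2))
    ray <- drop(ray) + c(lateral / dist, 0)
    ray <- ray / sqrt(sum(ray^2))
    t <- ray * dist - drop(R %*% centre)
    pose <- view_pose(R, t)
    uv <- tryCatch(project_points(camera, pose, grid),
                   error = function(e) NULL)
    if (is.null(uv)) next
    inside <- uv[, 1] >= 2 & uv[, 1] <= camera$width - 3 &
      uv[, 2] >= 2 & uv[, 2] <= camera$height - 3
    if (!all(inside)) next
    if (noise_sd > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_sd), nrow(uv))
    views[[i]] <- list(object = grid, image = uv[, 1:2, drop = FALSE],
                       pose = pose)
    i <- i + 1L
  }
  views
}

#' Read / write planar correspondences as CSV
#'
#' Column layout: `view_id, x3d, y3d, z3d, u, v` (metres and pixels).
#' @param path CSV path.
#' @return list of views as consumed by [calibrate_camera()].
#' @export
read_correspondences <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("view_id", "x3d", "y3d", "z3d", "u", "v") %in% names(d)))
  lapply(split(d, d$view_id), function(g)
    list(object = cbind(g$x3d, g$y3d, g$z3d), image = cbind(g$u, g$v)))
}

#' @rdname read_correspondences
#' @param views list of views (`object`, `image`).
#' @export
write_correspondences <- function(views, path) {
  if (is.null(names(views))) names(views) <- seq_along(views)
  d <- do.call(rbind, lapply(names(views), function(id) {
    v <- views[[id]]
    data.frame(view_id = id, x3d = v$object[, 1], y3d = v$object[, 2],
               z3d = v$object[, 3], u = v$image[, 1], v = v$image[, 2])
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
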