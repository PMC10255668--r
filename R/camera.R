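#' Pinhole camera with radial lens distortion
#'
#' The camera model used throughout: focal lengths and principal point in
#' pixels, optional skew, and a two-term radial distortion polynomial
#' `1 + k1 r^2 + k2 r^4` applied to normalised image coordinates
#' (tangential terms are carried but default to zero). Defaults are the
#' thermal camera's calibrated parameters.
#'
#' @param fx,fy focal lengths, pixels (> 0).
#' @param cx,cy principal point, pixels (0-based pixel coordinates, pixel
#'   centres at integers).
#' @param skew axis skew (default 0).
#' @param k1,k2 radial distortion coefficients (defaults -0.1004, -1.0318).
#' @param p1,p2 tangential distortion coefficients (default 0).
#' @param width,height image size in pixels (defaults 320 x 240).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx = 736.5414, fy = 742.3704,
                         cx = 274.4383, cy = 145.2130, skew = 0,
                         k1 = -0.1004, k2 = -1.0318, p1 = 0, p2 = 0,
                         width = 320L, height = 240L) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew,
                 k1 = k1, k2 = k2, p1 = p1, p2 = p2,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> f=(%.2f, %.2f) px, pp=(%.2f, %.2f), k=(%.4f, %.4f), %dx%d\n",
    x$fx, x$fy, x$cx, x$cy, x$k1, x$k2, x$width, x$height))
  invisible(x)
}

#' Rigid world-to-camera pose
#'
#' @param rotation 3 x 3 orthonormal world-to-camera rotation,
#'   det = +1, checked to 1e-9.
#' @param translation length-3 translation, metres (camera-frame point
#'   `p_c = R p_w + t`).
#' @return An object of class `view_pose`.
#' @export
view_pose <- function(rotation, translation) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal to 1e-9", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation has negative determinant (reflection)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "view_pose")
}

#' @export
print.view_pose <- function(x, ...) {
  aa <- rotation_to_axis_angle(x$rotation)
  cat(sprintf("<view_pose> angle %.2f deg, t = (%.3f, %.3f, %.3f) m\n",
              sqrt(sum(aa^2)) * 180 / pi,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# --- rotation helpers (Rodrigues) -------------------------------------------

#' Axis-angle (Rodrigues vector) to rotation matrix and back
#' @param v length-3 rotation vector (axis * angle, radians).
#' @return 3 x 3 rotation matrix.
#' @export
axis_angle_to_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname axis_angle_to_rotation
#' @param R 3 x 3 rotation matrix.
#' @export
rotation_to_axis_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # angle near pi: axis from the symmetric part
    B <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(B), 0))
    i <- which.max(k)
    if (k[i] > 0) {
      k <- B[, i] / k[i]
      k <- k / sqrt(sum(k^2))
    }
    return(k * th)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  w / (2 * sin(th)) * th
}

#' Quaternion conversions for pose serialisation
#' @param R 3 x 3 rotation matrix.
#' @return unit quaternion (w, x, y, z).
#' @export
rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' @rdname rotation_to_quaternion
#' @param q unit quaternion (w, x, y, z).
#' @export
quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# --- projection --------------------------------------------------------------

distort_normalized <- function(xn, yn, cam) {
  r2 <- xn^2 + yn^2
  f <- 1 + cam$k1 * r2 + cam$k2 * r2^2
  xd <- xn * f + 2 * cam$p1 * xn * yn + cam$p2 * (r2 + 2 * xn^2)
  yd <- yn * f + cam$p1 * (r2 + 2 * yn^2) + 2 * cam$p2 * xn * yn
  list(x = xd, y = yd)
}

#' Project world points to pixel coordinates
#'
#' Transforms to the camera frame, perspective-divides, applies radial (and
#' tangential, if set) distortion to the normalised coordinates, and maps
#' through the intrinsics. Pixel coordinates are 0-based with pixel centres
#' at integer coordinates; u grows rightwards, v downwards.
#'
#' @param camera a [camera_model()].
#' @param pose a [view_pose()].
#' @param points n x 3 matrix (or length-3 vector) of world points, metres.
#' @param allow_behind if `FALSE` (default), any non-positive camera-frame
#'   depth is an error; set `TRUE` to get NA rows instead.
#' @return n x 2 matrix of (u, v) pixels; attribute `"depth"` carries the
#'   camera-frame z of each point.
#' @export
project_points <- function(camera, pose, points, allow_behind = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  pc <- points %*% t(pose$rotation) +
    matrix(pose$translation, nrow(points), 3, byrow = TRUE)
  z <- pc[, 3]
  if (any(z <= 0)) {
    if (!allow_behind)
      stop(sprintf("%d point(s) at non-positive depth (behind the camera)",
                   sum(z <= 0)), call. = FALSE)
  }
  ok <- z > 0
  xn <- pc[, 1] / z; yn <- pc[, 2] / z
  d <- distort_normalized(xn, yn, camera)
  u <- camera$fx * d$x + camera$skew * d$y + camera$cx
  v <- camera$fy * d$y + camera$cy
  u[!ok] <- NA_real_; v[!ok] <- NA_real_
  out <- cbind(u = u, v = v)
  attr(out, "depth") <- z
  out
}

#' Undistort pixel coordinates to ideal pinhole pixels
#'
#' Inverts the radial distortion by Newton iteration on the normalised
#' radius, then remaps through the intrinsics, recovering the pixel the
#' ideal (distortion-free) pinhole camera would have produced.
#'
#' @param camera a [camera_model()].
#' @param uv n x 2 matrix of observed (distorted) pixel coordinates.
#' @param iterations Newton iterations (default 20).
#' @return n x 2 matrix of undistorted pixel coordinates.
#' @export
undistort_points <- function(camera, uv, iterations = 20L) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2, byrow = TRUE)
  yd <- (uv[, 2] - camera$cy) / camera$fy
  xd <- (uv[, 1] - camera$cx - camera$skew * yd) / camera$fx
  xn <- xd; yn <- yd
  for (i in seq_len(iterations)) {
    d <- distort_normalized(xn, yn, camera)
    xn <- xn - (d$x - xd); yn <- yn - (d$y - yd)
  }
  cbind(u = camera$fx * xn + camera$skew * yn + camera$cx,
        v = camera$fy * yn + camera$cy)
}

#' Normalised rays of pixel coordinates
#'
#' Undistorts pixels and returns unit direction vectors in the camera
#' frame (z forward).
#' @inheritParams undistort_points
#' @return n x 3 matrix of unit rays.
#' @export
pixel_rays <- function(camera, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2, byrow = TRUE)
  p <- undistort_points(camera, uv)
  yn <- (p[, 2] - camera$cy) / camera$fy
  xn <- (p[, 1] - camera$cx - camera$skew * yn) / camera$fx
  r <- cbind(xn, yn, 1)
  r / sqrt(rowSums(r^2))
}

#' Inner-corner grid of a planar chessboard target
#'
#' Generates the 3D coordinates (z = 0 plane, metres) of the inner corners
#' of a chessboard of the given physical size, row-major, with the origin
#' at a board corner so the first inner corner sits at
#' (square, square, 0).
#'
#' @param square_mm square edge, mm (default 30).
#' @param board_mm board size (width, height), mm (default c(300, 180)).
#' @return n x 3 matrix of corner coordinates, metres; attributes
#'   `"n_cols"`/`"n_rows"` give the grid dimensions.
#' @export
corner_grid <- function(square_mm = 30, board_mm = c(300, 180)) {
  stopifnot(square_mm > 0)
  nsq <- floor(board_mm / square_mm + 1e-9)
  nc <- nsq[1] - 1L; nr <- nsq[2] - 1L
  if (nc < 1 || nr < 1)
    stop(sprintf("board of %g x %g mm with %g mm squares has no inner corners",
                 board_mm[1], board_mm[2], square_mm), call. = FALSE)
  g <- expand.grid(x = seq_len(nc), y = seq_len(nr))
  out <- cbind(g$x * square_mm, g$y * square_mm, 0) / 1000
  attr(out, "n_cols") <- as.integer(nc)
  attr(out, "n_rows") <- as.integer(nr)
  out
}

#' Serialise / restore a camera model as JSON
#' @param camera a [camera_model()]; `path` a JSON path.
#' @export
write_camera_model <- function(camera, path) {
  jsonlite::write_json(
    list(focal_length = c(camera$fx, camera$fy),
         principal_point = c(camera$cx, camera$cy),
         skew = camera$skew,
         radial_distortion = c(camera$k1, camera$k2),
         tangential_distortion = c(camera$p1, camera$p2),
         image_size = c(camera$width, camera$height)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_model
#' @param path JSON path written by [write_camera_model()].
#' @export
read_camera_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(fx = j$focal_length[1], fy = j$focal_length[2],
               cx = j$principal_point[1], cy = j$principal_point[2],
               skew = j$skew,
               k1 = j$radial_distortion[1], k2 = j$radial_distortion[2],
               p1 = j$tangential_distortion[1], p2 = j$tangential_distortion[2],
               width = j$image_size[1], height = j$image_size[2])
}
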