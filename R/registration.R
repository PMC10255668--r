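#' Detect thermal fiducial blobs in a frame
#'
#' The hollow-cube markers image several degrees below the skin, so
#' thresholding the frame around the marker temperature segments them:
#' connected components (8-connectivity) of pixels within `tolerance` of
#' `marker_temperature`, components smaller than 3 px discarded, one
#' intensity-weighted centroid per component.
#'
#' @param frame a [thermal_frame()].
#' @param marker_temperature apparent marker temperature, degC
#'   (default 26).
#' @param tolerance half-width of the accepted band, degC (default 1).
#' @param min_pixels minimum blob size (default 3).
#' @return data.frame with columns `u`, `v` (pixel centroids, 0-based)
#'   and `n_pixels`; zero rows when nothing is found.
#' @export
detect_marker_blobs <- function(frame, marker_temperature = 26,
                                tolerance = 1, min_pixels = 3L) {
  stopifnot(inherits(frame, "thermal_frame"))
  mask <- abs(frame$values - marker_temperature) <= tolerance
  if (!any(mask))
    return(data.frame(u = numeric(0), v = numeric(0),
                      n_pixels = integer(0)))
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  rows <- row(mask)[lab > 0]; cols <- col(mask)[lab > 0]
  labs <- lab[lab > 0]
  size <- tabulate(labs, nbins = max(labs))
  u <- tapply(cols - 1, labs, mean)
  v <- tapply(rows - 1, labs, mean)
  keep <- size >= min_pixels
  data.frame(u = as.numeric(u[keep]), v = as.numeric(v[keep]),
             n_pixels = as.integer(size[keep]))
}

#' Estimate a camera pose from fiducial correspondences
#'
#' Perspective-n-point: given >= 3 non-collinear marker centres on the
#' mesh and their image centroids, recovers the 6-DoF world-to-camera
#' pose. Image points are undistorted to rays; a closed-form
#' initialisation (weak-perspective depth followed by orthogonal
#' iteration, i.e. alternating depths and an absolute-orientation fit) is
#' polished by Levenberg-Marquardt on the reprojection error. When an
#' `init` pose is supplied (e.g. the nominal rotating-platform pose) the
#' iteration starts there instead.
#'
#' @param observations list or data.frame with `image` (k x 2 pixels) and
#'   `object` (k x 3 world points, metres); k >= 3.
#' @param camera a [camera_model()].
#' @param init optional initial [view_pose()].
#' @param prior optional [view_pose()] to regularise towards (a
#'   maximum-a-posteriori fit). With three markers the pose is exactly
#'   determined, so any systematic centroid bias maps one-to-one into
#'   pose error — mostly in depth; when the acquisition geometry is
#'   known (fixed camera, stepped platform) the prior damps that mode.
#' @param prior_rot_sd,prior_trans_sd prior standard deviations, radians
#'   and metres (defaults 0.035 rad ~ 2 degrees, 10 mm).
#' @return list of class `pnp_result`: `pose` ([view_pose()]),
#'   `fiducial_rmse` (px), `n_points`.
#' @export
estimate_pose_from_fiducials <- function(observations, camera,
                                         init = NULL, prior = NULL,
                                         prior_rot_sd = 0.035,
                                         prior_trans_sd = 0.01) {
  P <- as.matrix(observations$object)
  uv <- as.matrix(observations$image)
  k <- nrow(P)
  if (is.null(k) || k < 3L)
    stop("pose estimation needs at least 3 marker observations",
         call. = FALSE)
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop("degenerate configuration: marker centres are collinear",
         call. = FALSE)

  rays <- pixel_rays(camera, uv)
  starts <- list()
  if (!is.null(init)) starts <- list(init)
  # common-depth start: match the spread of the object points to the
  # angular spread of the rays, then orthogonal iteration (alternate
  # ray depths with an absolute-orientation fit)
  dP <- stats::dist(P); dR <- stats::dist(rays)
  d0 <- mean(dP) / max(mean(dR), 1e-9)
  lambda <- rep(d0, k)
  R <- diag(3); t <- c(0, 0, d0)
  for (it in 1:100) {
    fit <- absolute_orientation(P, rays * lambda)
    R <- fit$R; t <- fit$t
    Yc <- P %*% t(R) + matrix(t, k, 3, byrow = TRUE)
    lambda_new <- pmax(rowSums(rays * Yc), 1e-6)
    if (max(abs(lambda_new - lambda)) < 1e-12) { lambda <- lambda_new; break }
    lambda <- lambda_new
  }
  starts <- c(starts, list(view_pose(R, t)))
  # fallback canonical starts: the orthogonal iteration occasionally
  # settles on the mirrored pose, so look-at poses from the six axis
  # directions at the estimated distance join the pool
  ctr <- colMeans(P)
  for (dir in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    eye <- ctr + dir * d0
    st <- tryCatch(look_at_pose(eye, ctr), error = function(e) NULL)
    if (!is.null(st)) starts <- c(starts, list(st))
  }

  resid <- function(par) {
    pose <- view_pose(axis_angle_to_rotation(par[1:3]), par[4:6])
    pr <- project_points(camera, pose, P, allow_behind = TRUE)
    r <- pr - uv
    r[is.na(r)] <- 1e4
    out <- as.vector(r)
    if (!is.null(prior)) {
      dr <- rotation_to_axis_angle(pose$rotation %*% t(prior$rotation))
      dt <- pose$translation - prior$translation
      out <- c(out, dr / prior_rot_sd, dt / prior_trans_sd)
    }
    out
  }
  resid_px <- function(par) {
    pose <- view_pose(axis_angle_to_rotation(par[1:3]), par[4:6])
    pr <- project_points(camera, pose, P, allow_behind = TRUE)
    r <- pr - uv
    r[is.na(r)] <- 1e4
    as.vector(r)
  }
  # three points admit up to four exact perspective solutions, so ties in
  # reprojection error are broken by closeness to the reference pose (the
  # supplied init, else the orthogonal-iteration estimate)
  ref <- starts[[1]]
  cand <- list()
  for (pose0 in starts) {
    par0 <- c(rotation_to_axis_angle(pose0$rotation), pose0$translation)
    fit <- minpack.lm::nls.lm(
      par = par0, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-14,
                                           ptol = 1e-14))
    rmse <- sqrt(mean(matrix(resid_px(fit$par), ncol = 2)^2 %*% c(1, 1)))
    cand[[length(cand) + 1]] <- list(par = fit$par, rmse = rmse)
    if (!is.null(init) || k > 3)
      if (rmse < 1e-10 && identical(pose0, ref)) break
  }
  rmses <- vapply(cand, `[[`, numeric(1), "rmse")
  tied <- which(rmses <= min(rmses) + 1e-6)
  dist_to_ref <- vapply(tied, function(i) {
    R <- axis_angle_to_rotation(cand[[i]]$par[1:3])
    a <- rotation_to_axis_angle(R %*% t(ref$rotation))
    sqrt(sum(a^2)) +
      sqrt(sum((cand[[i]]$par[4:6] - ref$translation)^2))
  }, numeric(1))
  best <- cand[[tied[which.min(dist_to_ref)]]]
  pose <- view_pose(axis_angle_to_rotation(best$par[1:3]), best$par[4:6])
  rmse <- best$rmse
  structure(list(pose = pose, fiducial_rmse = rmse, n_points = k),
            class = "pnp_result")
}

# Kabsch/Horn absolute orientation: rigid R, t with X2 ~ R X1 + t
absolute_orientation <- function(X1, X2) {
  c1 <- colMeans(X1); c2 <- colMeans(X2)
  H <- crossprod(sweep(X1, 2, c1), sweep(X2, 2, c2))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = drop(c2 - R %*% c1))
}

#' Mutual information between two images over a mask
#'
#' Joint-histogram mutual information in bits: both images are binned
#' into `bins` equal-width bins over their observed ranges within the
#' mask, and MI = H(X) + H(Y) - H(X, Y) is computed from the joint counts.
#'
#' @param x,y numeric matrices of identical size.
#' @param mask logical matrix selecting the overlap region (default: all
#'   pixels).
#' @param bins histogram bins per axis (default 32).
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y, mask = NULL, bins = 32L) {
  if (is.null(mask)) mask <- array(TRUE, dim(x))
  stopifnot(all(dim(x) == dim(y)), all(dim(x) == dim(mask)))
  xs <- x[mask]; ys <- y[mask]
  if (!length(xs)) stop("empty mask", call. = FALSE)
  bin <- function(v) {
    r <- range(v)
    if (r[2] - r[1] < 1e-300) return(rep(1L, length(v)))
    pmin(bins, pmax(1L, as.integer(floor((v - r[1]) / (r[2] - r[1]) *
                                           bins)) + 1L))
  }
  bx <- bin(xs); by <- bin(ys)
  joint <- table(factor(bx, levels = 1:bins), factor(by, levels = 1:bins))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  ent(px) + ent(py) - ent(as.vector(p))
}

#' Refine a pose by maximising mutual information
#'
#' Image-to-geometry refinement: renders a pose-dependent surface
#' attribute (Lambertian shading of the mesh from the camera direction,
#' which is pose-sensitive and correlates with the thermal shading of a
#' curved limb) and maximises the mutual information between the thermal
#' frame and the render over the rendered silhouette, by Nelder-Mead over
#' 6 pose increments (axis-angle, translation) with one restart from the
#' best point. The returned MI is never below the initial pose's.
#'
#' @param initial initial [view_pose()] (e.g. from fiducials).
#' @param frame the observed [thermal_frame()].
#' @param mesh the [limb_mesh()].
#' @param camera the [camera_model()].
#' @param rot_scale,trans_scale initial simplex scales, radians / metres
#'   (defaults 0.01 rad, 2 mm).
#' @param maxit Nelder-Mead evaluations per start (default 150).
#' @return list of class `registration_result`: `pose`, `mi_score`
#'   (bits), `mi_initial`, `converged`.
#' @export
refine_pose <- function(initial, frame, mesh, camera,
                        rot_scale = 0.01, trans_scale = 0.002,
                        maxit = 150L) {
  # the evaluation mask stays fixed at the initial silhouette: if it
  # tracked the candidate render, shrinking the silhouette would discard
  # the mixed boundary pixels and spuriously inflate MI (the classic
  # overlap pathology of MI registration)
  r0 <- render_attribute(mesh, shading_values(mesh, initial), camera,
                         initial, background = -1)
  mask0 <- r0$face > 0L
  if (!any(mask0))
    stop("initial pose renders an empty silhouette", call. = FALSE)
  score <- function(delta) {
    pose <- perturb_pose(initial, delta)
    r <- render_attribute(mesh, shading_values(mesh, pose), camera, pose,
                          background = -1)
    mutual_information(frame$values, r$image, mask0)
  }
  s0 <- score(rep(0, 6))
  # optimise in scaled variables; Nelder-Mead builds its first simplex
  # with steps of 10% of a unit, so a factor 10 makes the first probes
  # exactly rot_scale / trans_scale — large enough to step across the
  # histogram's sub-pixel plateaus
  scale <- 10 * c(rep(rot_scale, 3), rep(trans_scale, 3))
  best <- list(par = rep(0, 6), value = s0)
  conv <- FALSE
  for (round in 1:2) {
    opt <- stats::optim(best$par, function(s) -score(s * scale),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7))
    if (-opt$value > best$value) best <- list(par = opt$par,
                                              value = -opt$value)
    conv <- opt$convergence == 0L
  }
  structure(
    list(pose = perturb_pose(initial, best$par * scale),
         mi_score = best$value, mi_initial = s0, converged = conv),
    class = "registration_result")
}

perturb_pose <- function(pose, delta) {
  view_pose(axis_angle_to_rotation(delta[1:3]) %*% pose$rotation,
            pose$translation + delta[4:6])
}

#' Register one thermal view against the limb mesh
#'
#' The per-view registration used by the pipeline: detect marker blobs,
#' associate them with the mesh's marker centres by nearest projection
#' under the nominal platform pose, initialise with
#' [estimate_pose_from_fiducials()] (falling back to the platform pose
#' when fewer than 3 blobs are matched), and refine by mutual
#' information.
#'
#' @param frame a [thermal_frame()].
#' @param mesh the [limb_mesh()].
#' @param marker_centers k x 3 marker centres, metres.
#' @param camera the [camera_model()].
#' @param platform_pose the nominal pose of this view from the platform
#'   geometry (azimuth known from the view index).
#' @param marker_temperature,tolerance blob detection parameters.
#' @param refine run the MI refinement (default TRUE).
#' @param match_gate_px maximum blob-to-prediction distance for a match
#'   (default 12 px).
#' @return a `registration_result` with extra fields `fiducial_rmse`,
#'   `n_markers_used`.
#' @export
register_view <- function(frame, mesh, marker_centers, camera,
                          platform_pose, marker_temperature = 26,
                          tolerance = 1, refine = TRUE,
                          match_gate_px = 12) {
  blobs <- detect_marker_blobs(frame, marker_temperature, tolerance)
  cam_pos <- -drop(t(platform_pose$rotation) %*% platform_pose$translation)
  outward <- cbind(marker_centers[, 1], marker_centers[, 2], 0)
  outward <- outward / pmax(sqrt(rowSums(outward^2)), 1e-12)
  facing <- rowSums((matrix(cam_pos, nrow(marker_centers), 3,
                            byrow = TRUE) - marker_centers) * outward) > 0
  pred <- project_points(camera, platform_pose, marker_centers,
                         allow_behind = TRUE)
  obs <- NULL
  if (nrow(blobs) > 0 && any(facing)) {
    # greedy nearest matching with a distance gate
    cand <- expand.grid(b = seq_len(nrow(blobs)), m = which(facing))
    cand$d <- sqrt((blobs$u[cand$b] - pred[cand$m, 1])^2 +
                     (blobs$v[cand$b] - pred[cand$m, 2])^2)
    cand <- cand[order(cand$d), ]
    used_b <- used_m <- integer(0)
    pairs <- list()
    for (i in seq_len(nrow(cand))) {
      if (cand$d[i] > match_gate_px) break
      if (cand$b[i] %in% used_b || cand$m[i] %in% used_m) next
      pairs[[length(pairs) + 1]] <- c(cand$b[i], cand$m[i])
      used_b <- c(used_b, cand$b[i]); used_m <- c(used_m, cand$m[i])
    }
    if (length(pairs)) {
      pr <- do.call(rbind, pairs)
      obs <- list(image = cbind(blobs$u[pr[, 1]], blobs$v[pr[, 1]]),
                  object = marker_centers[pr[, 2], , drop = FALSE])
    }
  }
  n_used <- if (is.null(obs)) 0L else nrow(obs$image)
  if (n_used >= 3L) {
    # MAP fit: the rotating platform fixes the acquisition geometry, so
    # the nominal pose acts as a prior that damps the depth mode a
    # 3-marker fit leaves unconstrained
    pnp <- estimate_pose_from_fiducials(obs, camera,
                                        init = platform_pose,
                                        prior = platform_pose)
    pose0 <- pnp$pose; rmse <- pnp$fiducial_rmse
  } else {
    pose0 <- platform_pose; rmse <- NA_real_
  }
  blob_rmse <- function(pose) {
    if (is.null(obs) || n_used < 2L) return(NA_real_)
    pr <- project_points(camera, pose, obs$object, allow_behind = TRUE)
    sqrt(mean(rowSums((pr - obs$image)^2), na.rm = TRUE))
  }
  res <- if (refine) refine_pose(pose0, frame, mesh, camera)
         else structure(list(pose = pose0, mi_score = NA_real_,
                             mi_initial = NA_real_, converged = TRUE),
                        class = "registration_result")
  res$refine_reverted <- FALSE
  if (refine && is.finite(blob_rmse(pose0))) {
    # consistency gate: the refinement may not contradict the fiducial
    # evidence — if it degrades the blob reprojection by more than a
    # pixel, keep the fiducial pose
    if (blob_rmse(res$pose) > blob_rmse(pose0) + 1.0) {
      res$pose <- pose0
      res$refine_reverted <- TRUE
    }
  }
  res$fiducial_rmse <- rmse
  res$n_markers_used <- n_used
  res
}

#' Serialise per-view registration results as JSON
#' @param results named list of `registration_result`s.
#' @param path JSON path.
#' @export
write_registration_report <- function(results, path) {
  jsonlite::write_json(
    lapply(results, function(r)
      list(quaternion = rotation_to_quaternion(r$pose$rotation),
           translation = r$pose$translation,
           mi_score = r$mi_score, mi_initial = r$mi_initial,
           fiducial_rmse = r$fiducial_rmse,
           n_markers_used = r$n_markers_used,
           converged = r$converged)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
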