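#' Per-vertex visibility and view weights
#'
#' For every mesh vertex and registered view: the vertex is visible iff
#' its projection falls inside the image, it faces the camera
#' (normal . view-direction > 0), and the ray from the vertex to the
#' camera centre hits no nearer geometry (occlusion test, eps = 1e-5 m).
#' The view weight is the cosine of the angle between the vertex normal
#' and the view direction (0 when invisible); the best view per vertex is
#' the visible one with the largest weight.
#'
#' @param mesh a [limb_mesh()].
#' @param camera a [camera_model()].
#' @param poses list of registered [view_pose()]s (>= 1).
#' @return list of class `view_assignment`: `visible` (n x V logical),
#'   `weight` (n x V), `uv` (list of n x 2 projections), `best`
#'   (n integers, NA when invisible everywhere).
#' @export
compute_visibility <- function(mesh, camera, poses) {
  if (length(poses) < 1L) stop("need at least one registered view",
                               call. = FALSE)
  n <- nrow(mesh$vertices)
  V <- length(poses)
  vis <- matrix(FALSE, n, V)
  wt <- matrix(0, n, V)
  uvs <- vector("list", V)
  for (j in seq_len(V)) {
    pose <- poses[[j]]
    uv <- project_points(camera, pose, mesh$vertices, allow_behind = TRUE)
    uvs[[j]] <- uv
    cam_pos <- -drop(t(pose$rotation) %*% pose$translation)
    dirs <- sweep(-mesh$vertices, 2, cam_pos, "+")  # vertex -> camera
    dist <- sqrt(rowSums(dirs^2))
    dirs <- dirs / dist
    cosang <- rowSums(mesh$normals * dirs)
    inside <- !is.na(uv[, 1]) &
      uv[, 1] >= 0 & uv[, 1] <= camera$width - 1 &
      uv[, 2] >= 0 & uv[, 2] <= camera$height - 1
    cand <- which(inside & cosang > 0)
    if (length(cand)) {
      occ <- ray_occluded_cpp(mesh$vertices[cand, , drop = FALSE],
                              dirs[cand, , drop = FALSE],
                              dist[cand], mesh$vertices, mesh$faces,
                              eps = 1e-5)
      ok <- cand[!occ]
      vis[ok, j] <- TRUE
      wt[ok, j] <- cosang[ok]
    }
  }
  best <- apply(wt, 1, function(w) if (any(w > 0)) which.max(w)
                else NA_integer_)
  structure(list(visible = vis, weight = wt, uv = uvs, best = best),
            class = "view_assignment")
}

bilinear_sample <- function(img, u, v, valid = NULL) {
  # img: H x W x 3, 0-based pixel centres at integers; `valid` optionally
  # masks foreground pixels — background taps are excluded and the
  # remaining tap weights renormalised (silhouette pixels otherwise bleed
  # background colour onto grazing-angle vertices)
  H <- dim(img)[1]; W <- dim(img)[2]
  u <- pmin(pmax(u, 0), W - 1); v <- pmin(pmax(v, 0), H - 1)
  u0 <- pmin(floor(u), W - 2); v0 <- pmin(floor(v), H - 2)
  fu <- u - u0; fv <- v - v0
  taps <- list(list(cbind(v0 + 1, u0 + 1), (1 - fv) * (1 - fu)),
               list(cbind(v0 + 1, u0 + 2), (1 - fv) * fu),
               list(cbind(v0 + 2, u0 + 1), fv * (1 - fu)),
               list(cbind(v0 + 2, u0 + 2), fv * fu))
  out <- matrix(0, length(u), 3)
  wsum <- numeric(length(u))
  for (tp in taps) {
    w <- tp[[2]]
    if (!is.null(valid)) w <- w * valid[tp[[1]]]
    for (k in 1:3) out[, k] <- out[, k] + w * img[, , k][tp[[1]]]
    wsum <- wsum + w
  }
  ok <- wsum > 1e-9
  out[ok, ] <- out[ok, , drop = FALSE] / wsum[ok]
  out[!ok, ] <- NA_real_
  out
}

#' Transfer encoded image colours to mesh vertices
#'
#' Projects each vertex into its assigned view(s) and samples the encoded
#' colour image bilinearly. With `blend = TRUE` (default) all views that
#' see the vertex contribute, weighted by their visibility cosines — this
#' smooths view seams exactly the way texture-transfer smoothing does,
#' and thereby produces blended colours that are not in the colour table.
#' With `blend = FALSE` only the best view is sampled. Vertices invisible
#' in every view get the reserved sentinel colour (0,0,0).
#'
#' @param mesh a [limb_mesh()].
#' @param images list of H x W x 3 encoded images (one per pose; between
#'   1 and 10, the texturing limit).
#' @param assignment a [compute_visibility()] result for the same poses.
#' @param blend blend across views (default TRUE).
#' @param masks optional list of logical H x W foreground masks (one per
#'   view); background taps are then excluded from sampling.
#' @param min_weight minimum visibility cosine for a view to contribute
#'   (default 0.2, i.e. incidence up to ~78 degrees); vertices seen only
#'   at extreme grazing angles are left untextured rather than given
#'   smeared silhouette colours.
#' @return the mesh with `vertex_rgb` set (8-bit integers).
#' @export
assign_vertex_colors <- function(mesh, images, assignment, blend = TRUE,
                                 masks = NULL, min_weight = 0.2) {
  V <- length(images)
  if (V < 1L) stop("no images", call. = FALSE)
  if (V > 10L)
    stop(sprintf("texturing accepts at most 10 images (got %d)", V),
         call. = FALSE)
  stopifnot(ncol(assignment$visible) == V)
  n <- nrow(mesh$vertices)
  acc <- matrix(0, n, 3); wsum <- numeric(n)
  for (j in seq_len(V)) {
    sel <- which(if (blend)
                   assignment$visible[, j] &
                     assignment$weight[, j] >= min_weight
                 else !is.na(assignment$best) & assignment$best == j &
                     assignment$weight[, j] >= min_weight)
    if (!length(sel)) next
    uv <- assignment$uv[[j]]
    cols <- bilinear_sample(images[[j]], uv[sel, 1], uv[sel, 2],
                            valid = if (!is.null(masks)) masks[[j]])
    ok <- is.finite(cols[, 1])
    sel <- sel[ok]; cols <- cols[ok, , drop = FALSE]
    if (!length(sel)) next
    w <- if (blend) assignment$weight[sel, j] else 1
    acc[sel, ] <- acc[sel, ] + cols * w
    wsum[sel] <- wsum[sel] + w
  }
  textured <- wsum > 0
  rgb <- matrix(0L, n, 3)
  rgb[textured, ] <- matrix(
    as.integer(floor(acc[textured, , drop = FALSE] /
                       wsum[textured] + 0.5)), ncol = 3)
  # the sentinel (0,0,0) is reserved for untextured vertices; nudge any
  # genuine pure-black sample off it
  black <- textured & rgb[, 1] == 0L & rgb[, 2] == 0L & rgb[, 3] == 0L
  rgb[black, 3] <- 1L
  mesh$vertex_rgb <- rgb
  mesh
}

#' Convert vertex colours to vertex temperatures
#'
#' Applies the inverse colour model to every textured vertex; sentinel
#' (untextured) vertices get `NA` and are excluded from any temperature
#' statistics downstream.
#'
#' @param mesh a [limb_mesh()] with `vertex_rgb`.
#' @param model a trained [train_inverse_model()].
#' @return the mesh with `vertex_temperature` set.
#' @export
colors_to_temperatures <- function(mesh, model) {
  if (is.null(mesh$vertex_rgb))
    stop(sprintf("no vertex colours on this mesh (%d vertices): run assign_vertex_colors first",
                 nrow(mesh$vertices)), call. = FALSE)
  sentinel <- rowSums(mesh$vertex_rgb) == 0L
  temp <- rep(NA_real_, nrow(mesh$vertices))
  if (any(!sentinel))
    temp[!sentinel] <- rgb_to_temperature(model,
                                          mesh$vertex_rgb[!sentinel, ,
                                                          drop = FALSE])
  mesh$vertex_temperature <- temp
  mesh
}
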