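#' Differential 3D thermal map
#'
#' Per-vertex temperature difference between two conditions textured onto
#' the same 3D model (e.g. post-walk minus rest). Vertices lacking a
#' temperature in either input are missing in the output. The map is
#' colour-coded with the jet colormap stretched linearly over the observed
#' difference range, so the minimum difference takes the first colormap
#' row and the maximum the last.
#'
#' @param mesh_a,mesh_b [limb_mesh()]es with `vertex_temperature`, same
#'   vertex count and ordering (condition A minus condition B).
#' @return An object of class `differential_map`: `mesh` (geometry of A),
#'   `delta_t` (degC per vertex, NA where missing), `rgb` (8-bit colours),
#'   `range` (observed min/max of the finite differences).
#' @export
differential_map <- function(mesh_a, mesh_b) {
  stopifnot(inherits(mesh_a, "limb_mesh"), inherits(mesh_b, "limb_mesh"))
  if (nrow(mesh_a$vertices) != nrow(mesh_b$vertices))
    stop(sprintf("vertex-count mismatch: %d vs %d",
                 nrow(mesh_a$vertices), nrow(mesh_b$vertices)),
         call. = FALSE)
  if (is.null(mesh_a$vertex_temperature) ||
      is.null(mesh_b$vertex_temperature))
    stop("both meshes need vertex temperatures", call. = FALSE)
  dt <- mesh_a$vertex_temperature - mesh_b$vertex_temperature
  ok <- is.finite(dt)
  rng <- if (any(ok)) range(dt[ok]) else c(NA_real_, NA_real_)
  rgb <- matrix(0L, length(dt), 3)
  if (any(ok)) {
    span <- max(rng[2] - rng[1], 1e-12)
    x <- (dt[ok] - rng[1]) / span
    rgb[ok, ] <- jet_rgb(x)
  }
  structure(list(mesh = mesh_a, delta_t = dt, rgb = rgb, range = rng),
            class = "differential_map")
}

#' @export
print.differential_map <- function(x, ...) {
  ok <- is.finite(x$delta_t)
  cat(sprintf(
    "<differential_map> %d vertices (%d missing), dT %.2f..%.2f degC\n",
    length(x$delta_t), sum(!ok), x$range[1], x$range[2]))
  invisible(x)
}

#' Registration error from marker halos
#'
#' The markers keep an (almost) constant temperature across conditions,
#' so each marker leaves a near-zero patch ("halo") in the differential
#' map while the surrounding skin changes. Any displacement of that halo
#' from the marker's true centre measures the combined registration error
#' of the two conditions. Per marker: the vertices within `search_radius`
#' whose |dT| <= `zero_tolerance` form the halo; the Euclidean distance
#' from the marker centre to the halo centroid (in mm) is the marker's
#' misalignment. Markers with no halo are reported missing and excluded.
#'
#' @param diff a [differential_map()].
#' @param marker_centers k x 3 matrix of marker centres, metres.
#' @param search_radius halo search radius, m (default 0.015).
#' @param zero_tolerance |dT| accepted as "unchanged", degC (default 0.3,
#'   about 4x the sensor noise floor).
#' @return An object of class `registration_error_stats`: `per_marker`
#'   (data.frame: marker, distance_mm, n_halo), `median_mm`, `sd_mm`,
#'   `min_mm`, `max_mm`, `n_missing`.
#' @export
marker_halo_error <- function(diff, marker_centers, search_radius = 0.015,
                              zero_tolerance = 0.3) {
  stopifnot(inherits(diff, "differential_map"))
  marker_centers <- matrix(marker_centers, ncol = 3)
  if (nrow(marker_centers) < 1) stop("need at least one marker",
                                     call. = FALSE)
  V <- diff$mesh$vertices
  res <- lapply(seq_len(nrow(marker_centers)), function(i) {
    d2 <- rowSums(sweep(V, 2, marker_centers[i, ])^2)
    halo <- which(d2 <= search_radius^2 &
                    is.finite(diff$delta_t) &
                    abs(diff$delta_t) <= zero_tolerance)
    if (!length(halo))
      return(data.frame(marker = i, distance_mm = NA_real_, n_halo = 0L))
    centroid <- colMeans(V[halo, , drop = FALSE])
    data.frame(marker = i,
               distance_mm = 1000 * sqrt(sum((centroid -
                                                marker_centers[i, ])^2)),
               n_halo = length(halo))
  })
  per <- do.call(rbind, res)
  d <- per$distance_mm[!is.na(per$distance_mm)]
  if (!length(d))
    warning("no marker produced a halo; statistics are empty")
  structure(
    list(per_marker = per,
         median_mm = if (length(d)) stats::median(d) else NA_real_,
         sd_mm = if (length(d) > 1) stats::sd(d) else NA_real_,
         min_mm = if (length(d)) min(d) else NA_real_,
         max_mm = if (length(d)) max(d) else NA_real_,
         n_missing = sum(is.na(per$distance_mm))),
    class = "registration_error_stats")
}

#' @export
print.registration_error_stats <- function(x, ...) {
  cat(sprintf(
    "<registration_error_stats> median %.2f mm (sd %.2f, range %.2f-%.2f mm, %d markers, %d missing)\n",
    x$median_mm, x$sd_mm, x$min_mm, x$max_mm, nrow(x$per_marker),
    x$n_missing))
  invisible(x)
}

#' Hot-spot summary of a temperature map
#'
#' Connected components of vertices whose temperature exceeds the
#' threshold, with vertex count, surface area (one-third face-area
#' accumulation per vertex) and peak temperature.
#'
#' @param mesh a [limb_mesh()] with `vertex_temperature`.
#' @param threshold degC.
#' @return data.frame with one row per component (possibly empty):
#'   `component`, `n_vertices`, `area_m2`, `peak_c`.
#' @export
summarize_hotspots <- function(mesh, threshold) {
  if (is.null(mesh$vertex_temperature))
    stop("no vertex temperatures", call. = FALSE)
  hot <- which(is.finite(mesh$vertex_temperature) &
                 mesh$vertex_temperature > threshold)
  if (!length(hot))
    return(data.frame(component = integer(0), n_vertices = integer(0),
                      area_m2 = numeric(0), peak_c = numeric(0)))
  # vertex area: one third of each incident face
  fa <- face_areas(mesh)
  va <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    s <- rowsum(fa / 3, group = mesh$faces[, k])
    va[as.integer(rownames(s))] <- va[as.integer(rownames(s))] + s
  }
  g <- vertex_adjacency_graph(mesh)
  sub <- igraph::induced_subgraph(g, hot)
  comp <- igraph::components(sub)
  do.call(rbind, lapply(seq_len(comp$no), function(ci) {
    vs <- hot[comp$membership == ci]
    data.frame(component = ci, n_vertices = length(vs),
               area_m2 = sum(va[vs]),
               peak_c = max(mesh$vertex_temperature[vs]))
  }))
}

#' Write the differential map as PLY and its statistics as JSON
#' @param diff a [differential_map()]; `stats` a
#'   [marker_halo_error()] result; `path`/`json_path` output paths.
#' @export
write_differential_ply <- function(diff, path, binary = TRUE) {
  mesh <- diff$mesh
  mesh$vertex_rgb <- diff$rgb
  mesh$vertex_temperature <- NULL
  write_ply(mesh, path, binary = binary,
            scalars = list(delta_t = diff$delta_t))
  invisible(path)
}

#' @rdname write_differential_ply
#' @export
write_error_stats <- function(stats, json_path) {
  jsonlite::write_json(
    list(median_mm = stats$median_mm, sd_mm = stats$sd_mm,
         min_mm = stats$min_mm, max_mm = stats$max_mm,
         n_missing = stats$n_missing,
         per_marker = stats$per_marker),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  invisible(json_path)
}
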