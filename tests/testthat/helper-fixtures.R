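# Shared fixtures, built in code. Unit tests use a reduced-resolution
# scene so the whole suite stays fast; the acceptance tests use the full
# default resolution.

ramp_frame <- function() {
  thermal_frame(matrix(seq(28, 37, length.out = 240 * 320), 240, 320),
                view_id = "ramp")
}

ramp_color_table <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_color_table(list(ramp_frame()))
    val
  }
})

# small scene: ~4000 vertices, cached across tests
small_scene <- local({
  val <- NULL
  function(noise_sd = 0) {
    key <- as.character(noise_sd)
    if (is.null(val)) val <<- list()
    if (is.null(val[[key]]))
      val[[key]] <<- simulate_scene(
        seed = 1L, spec = limb_spec(mesh_resolution = 4000L),
        noise_sd = noise_sd)
    val[[key]]
  }
})

rotation_angle_deg <- function(R1, R2) {
  sqrt(sum(rotation_to_axis_angle(R1 %*% t(R2))^2)) * 180 / pi
}

# independent Moller-Trumbore ray/triangle oracle, plain R
ray_triangle_oracle <- function(orig, dir, v0, v1, v2) {
  e1 <- v1 - v0; e2 <- v2 - v0
  p <- c(dir[2] * e2[3] - dir[3] * e2[2],
         dir[3] * e2[1] - dir[1] * e2[3],
         dir[1] * e2[2] - dir[2] * e2[1])
  det <- sum(e1 * p)
  if (abs(det) < 1e-14) return(NA_real_)
  tv <- orig - v0
  u <- sum(tv * p) / det
  if (u < 0 || u > 1) return(NA_real_)
  q <- c(tv[2] * e1[3] - tv[3] * e1[2],
         tv[3] * e1[1] - tv[1] * e1[3],
         tv[1] * e1[2] - tv[2] * e1[1])
  v <- sum(dir * q) / det
  if (v < 0 || u + v > 1) return(NA_real_)
  sum(e2 * q) / det
}

# closest hit over all faces, plain R loop (oracle for the C++ grid)
ray_mesh_oracle <- function(orig, dir, V, F, tmin = 1e-9) {
  best <- Inf
  for (f in seq_len(nrow(F))) {
    t <- ray_triangle_oracle(orig, dir, V[F[f, 1], ], V[F[f, 2], ],
                             V[F[f, 3], ])
    if (!is.na(t) && t > tmin && t < best) best <- t
  }
  if (is.finite(best)) best else NA_real_
}

uv_sphere <- function(n_theta, n_phi, radius = 1) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 2)[-c(1, n_phi + 2)]
  g <- expand.grid(ph = ph, th = th)
  V <- radius * cbind(sin(g$ph) * cos(g$th), sin(g$ph) * sin(g$th),
                      cos(g$ph))
  np <- n_theta * n_phi
  V <- rbind(V, c(0, 0, radius), c(0, 0, -radius))
  idx <- function(i, j) ((j - 1L) %% n_theta) * n_phi + i
  F <- vector("list", n_theta)
  for (j in seq_len(n_theta)) {
    jn <- j + 1L
    i <- seq_len(n_phi - 1L)
    F[[j]] <- rbind(
      cbind(idx(i, j), idx(i, jn), idx(i + 1L, j)),
      cbind(idx(i + 1L, j), idx(i, jn), idx(i + 1L, jn)),
      c(np + 1L, idx(1L, j), idx(1L, jn)),
      c(np + 2L, idx(n_phi, jn), idx(n_phi, j)))
  }
  F <- do.call(rbind, F)
  # orient every face outward (normal towards the face centroid)
  a <- V[F[, 1], ]; e1 <- V[F[, 2], ] - a; e2 <- V[F[, 3], ] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ctr <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  flip <- rowSums(n * ctr) < 0
  F[flip, ] <- F[flip, c(1, 3, 2)]
  list(V = V, F = F)
}
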