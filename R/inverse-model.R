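#' Inverse colour model: rgb to temperature by grown radial-basis fit
#'
#' Inverts the anchored jet encoding. Half of the colour-table rows (seeded
#' random split) are used for fitting, the other half for validation, and
#' Gaussian radial-basis centres are added greedily at the worst-residual
#' training row — mirroring the grow-until-error behaviour of classic RBF
#' network training — until the mean squared error on the held-out half
#' drops to `mse_threshold` (default 1e-4 degC^2, i.e. 0.01 degC RMSE) or
#' the centre cap is hit, in which case training fails with the best MSE
#' reported.
#'
#' The regression does not operate on raw rgb coordinates: the colormap arc
#' has right-angle bends and 8-bit quantisation jitter that make a generic
#' smooth interpolant in rgb space irreducibly inaccurate between table
#' rows. Because the encoder is the package's own, each query colour is
#' first projected onto the known palette polyline, giving a fractional
#' palette coordinate `u` in \[0, 1\]; the RBF (plus a linear tail) is then
#' grown in `u`. Off-arc colours — produced when texturing blends adjacent
#' views — project to the nearest point of the arc and so still receive a
#' finite, sensible temperature.
#'
#' @param table a `color_table` from [build_color_table()] (>= 4 rows).
#' @param split_seed integer seed for the 50/50 row split.
#' @param mse_threshold stopping mean squared error on the held-out half,
#'   degC^2 (default `1e-4`).
#' @param spread Gaussian radius in palette-coordinate units (default 0.02,
#'   a few palette steps, so neighbouring centres overlap strongly).
#' @param max_centers hard cap on centres (default 200).
#' @param spec the [colormap_spec()] the table was built under; its palette
#'   polyline is the projection target and its anchors the output clip
#'   range.
#' @return An object of class `inverse_color_model` with elements
#'   `centers` (in palette coordinate), `weights` (RBF weights, then the
#'   linear-tail slope and intercept), `spread`, `train_mse`, `test_mse`,
#'   `mse_threshold`, `split_seed`, `t_low`, `t_high`, `n_levels`.
#' @export
train_inverse_model <- function(table, split_seed = 1L,
                                mse_threshold = 1e-4, spread = 0.02,
                                max_centers = 200L,
                                spec = colormap_spec()) {
  stopifnot(inherits(table, "color_table"))
  n <- nrow(table)
  if (n < 4L) stop("colour table needs at least 4 rows", call. = FALSE)
  rgb <- as.matrix(table[, c("r", "g", "b")])
  y <- table$temperature

  u <- palette_coordinate(rgb, spec)
  set.seed(split_seed)
  idx_train <- sort(sample.int(n, floor(n / 2)))
  idx_test <- setdiff(seq_len(n), idx_train)
  utr <- u[idx_train]; ytr <- y[idx_train]
  ute <- u[idx_test]; yte <- y[idx_test]

  design <- function(uu, centers)
    cbind(exp(-outer(uu, centers, "-")^2 / spread^2), uu, 1)
  fit_weights <- function(A, yy) {
    # small ridge: centres become near-duplicates as the greedy pass
    # fills in the arc
    M <- crossprod(A) + diag(1e-8, ncol(A))
    drop(solve(M, crossprod(A, yy)))
  }

  centers_idx <- integer(0)
  best <- list(test_mse = Inf)
  resid <- ytr - mean(ytr)
  repeat {
    open <- setdiff(seq_along(ytr), centers_idx)
    centers_idx <- c(centers_idx, open[which.max(abs(resid[open]))])
    w <- fit_weights(design(utr, utr[centers_idx]), ytr)
    resid <- ytr - drop(design(utr, utr[centers_idx]) %*% w)
    rte <- yte - drop(design(ute, utr[centers_idx]) %*% w)
    train_mse <- mean(resid^2)
    test_mse <- mean(rte^2)
    if (test_mse < best$test_mse)
      best <- list(centers = utr[centers_idx], weights = w,
                   train_mse = train_mse, test_mse = test_mse)
    # stop on the mean-squared criterion, but also require the worst
    # held-out residual to stay below half a palette quantisation step so
    # the per-level round-trip bound holds, not just on average
    if (test_mse <= mse_threshold &&
        max(abs(rte)) <= 1.5 * sqrt(mse_threshold)) break
    if (length(centers_idx) >= min(max_centers, length(ytr)))
      stop(sprintf(
        "inverse model did not reach held-out MSE %.1e within %d centres (best %.3e)",
        mse_threshold, max_centers, best$test_mse), call. = FALSE)
  }

  structure(
    list(centers = best$centers, weights = best$weights, spread = spread,
         train_mse = best$train_mse, test_mse = best$test_mse,
         mse_threshold = mse_threshold, split_seed = split_seed,
         t_low = spec$t_low, t_high = spec$t_high,
         n_levels = spec$n_levels),
    class = "inverse_color_model")
}

#' Fractional palette coordinate of rgb colours
#'
#' Projects 8-bit colours onto the polyline through the discrete palette
#' colours of `spec` and returns the fractional level position scaled to
#' \[0, 1\]: exact palette colours map to their level exactly, a 50/50
#' blend of two adjacent palette colours to the midpoint between their
#' levels, and arbitrary colours to the nearest point of the arc.
#'
#' @param rgb n x 3 matrix (or length-3 vector) of 8-bit values.
#' @param spec a [colormap_spec()].
#' @return numeric vector in \[0, 1\].
#' @export
palette_coordinate <- function(rgb, spec = colormap_spec()) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  P <- rgb / 255
  N <- jet_palette(spec) / 255
  m <- nrow(N)
  segs <- N[-1, , drop = FALSE] - N[-m, , drop = FALSE]
  len2 <- rowSums(segs^2)
  best_u <- numeric(nrow(P)); best_d <- rep(Inf, nrow(P))
  for (j in seq_len(m - 1)) {
    if (len2[j] < 1e-20) next
    rel <- sweep(P, 2, N[j, ])
    tt <- pmin(1, pmax(0, drop(rel %*% segs[j, ]) / len2[j]))
    d <- rowSums((rel - outer(tt, segs[j, ]))^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_u[upd] <- (j - 1 + tt[upd]) / (m - 1)
  }
  best_u
}

#' @export
print.inverse_color_model <- function(x, ...) {
  cat(sprintf(
    "<inverse_color_model> %d centres, spread %.3g, train MSE %.3e, held-out MSE %.3e\n",
    length(x$centers), x$spread, x$train_mse, x$test_mse))
  invisible(x)
}

#' Convert rgb colours to temperatures
#'
#' Evaluates the inverse colour model and clips to the anchor range, so any
#' 8-bit colour — including blended off-palette colours — maps to a finite
#' temperature inside the encoding's range.
#'
#' @param model a trained [train_inverse_model()] result.
#' @param rgb integer vector of length 3 or n x 3 matrix, 8-bit values.
#' @return numeric vector of temperatures, degC.
#' @export
rgb_to_temperature <- function(model, rgb) {
  if (!inherits(model, "inverse_color_model") || is.null(model$weights))
    stop("model is not a trained inverse colour model", call. = FALSE)
  spec <- colormap_spec(model$t_low, model$t_high, model$n_levels)
  u <- palette_coordinate(rgb, spec)
  A <- cbind(exp(-outer(u, model$centers, "-")^2 / model$spread^2), u, 1)
  pmin(model$t_high, pmax(model$t_low, drop(A %*% model$weights)))
}

#' Persist / restore an inverse colour model as JSON
#' @param model a trained model; `path` a JSON path.
#' @export
write_inverse_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_inverse_model
#' @param path JSON path written by [write_inverse_model()].
#' @export
read_inverse_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(j, class = "inverse_color_model")
}
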