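#' Anchored jet colormap specification
#'
#' The encoding that turns temperatures into false colour. Temperatures are
#' clipped ("saturated") at the anchors, normalised to \[0, 1\] and mapped
#' through a continuous jet formula sampled at `n_levels` points:
#' \deqn{r(x) = clamp(1.5 - |4x - 3|),\quad
#'       g(x) = clamp(1.5 - |4x - 2|),\quad
#'       b(x) = clamp(1.5 - |4x - 1|)}
#' each clamped to \[0, 1\] and quantised to 8 bits (round half up). The
#' endpoints are the classic half-intensity blue (0,0,128) and red (128,0,0).
#'
#' @param t_low,t_high saturation anchors in degC; defaults 28 and 37, the
#'   anchors used for skin thermography of the residual limb.
#' @param n_levels number of discrete colours (default 256).
#' @return An object of class `colormap_spec`.
#' @export
colormap_spec <- function(t_low = 28, t_high = 37, n_levels = 256L) {
  stopifnot(is.numeric(t_low), is.numeric(t_high), t_low < t_high,
            n_levels >= 2)
  structure(list(t_low = t_low, t_high = t_high,
                 n_levels = as.integer(n_levels)),
            class = "colormap_spec")
}

clamp01 <- function(v) pmin(1, pmax(0, v))

#' Continuous jet colour at normalised position x in \[0,1\]
#' @param x numeric vector in \[0, 1\].
#' @return matrix with columns r, g, b of 8-bit integers.
#' @export
jet_rgb <- function(x) {
  r <- clamp01(1.5 - abs(4 * x - 3))
  g <- clamp01(1.5 - abs(4 * x - 2))
  b <- clamp01(1.5 - abs(4 * x - 1))
  m <- cbind(r = floor(r * 255 + 0.5), g = floor(g * 255 + 0.5),
             b = floor(b * 255 + 0.5))
  storage.mode(m) <- "integer"
  m
}

#' The discrete palette of a colormap spec
#' @param spec a [colormap_spec()].
#' @return `n_levels` x 3 integer matrix of 8-bit rgb rows, first row the
#'   colour of `t_low`, last row the colour of `t_high`.
#' @export
jet_palette <- function(spec) {
  jet_rgb(seq(0, 1, length.out = spec$n_levels))
}

#' Temperatures of the palette levels
#' @param spec a [colormap_spec()].
#' @return numeric vector of length `n_levels`.
#' @export
palette_temperatures <- function(spec) {
  seq(spec$t_low, spec$t_high, length.out = spec$n_levels)
}

temperature_to_level <- function(temps, spec) {
  x <- (pmin(spec$t_high, pmax(spec$t_low, temps)) - spec$t_low) /
    (spec$t_high - spec$t_low)
  as.integer(floor(x * (spec$n_levels - 1) + 0.5)) + 1L
}

#' Encode temperatures as 8-bit jet colours
#'
#' Vectorised scalar form of the frame encoder: each temperature is clipped
#' to the anchors and mapped to the nearest palette level.
#'
#' @param temps numeric vector of temperatures, degC.
#' @param spec a [colormap_spec()].
#' @return length(temps) x 3 integer matrix of rgb values.
#' @export
encode_temperature <- function(temps, spec = colormap_spec()) {
  pal <- jet_palette(spec)
  pal[temperature_to_level(temps, spec), , drop = FALSE]
}

#' Encode a thermal frame as a colour image
#'
#' Produces the 240 x 320 x 3 8-bit rgb array of the frame under the
#' anchored jet encoding (the colour-coded PNG of the workflow).
#'
#' @param frame a [thermal_frame()].
#' @param spec a [colormap_spec()].
#' @return integer array H x W x 3 with values in 0..255.
#' @export
encode_frame <- function(frame, spec = colormap_spec()) {
  stopifnot(inherits(frame, "thermal_frame"))
  rgb <- encode_temperature(as.vector(frame$values), spec)
  img <- array(0L, dim = c(nrow(frame$values), ncol(frame$values), 3L))
  for (k in 1:3) img[, , k] <- matrix(rgb[, k], nrow(frame$values))
  img
}

#' Write / read an encoded colour image as PNG
#' @param img integer H x W x 3 array with values 0..255.
#' @param path output PNG path.
#' @return `path` invisibly, or for the reader the integer array.
#' @export
write_encoded_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_encoded_png
#' @export
read_encoded_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  img <- array(as.integer(floor(a[, , 1:3] * 255 + 0.5)), dim = dim(a)[1:3])
  img
}

#' Build the deduplicated temperature-to-colour table
#'
#' Tabulates every (temperature, rgb) pair occurring in the frames under the
#' given encoding, orders by temperature and removes duplicates. Pairing
#' uses the saturated temperature (the value the colour actually encodes),
#' temperatures are compared at 0.01 degC resolution, and when several
#' distinct temperatures share one rgb code they are replaced by a single
#' row at their arithmetic mean, yielding a 1:1 table of unique temperatures
#' against unique rgb codes.
#'
#' @param frames list of [thermal_frame()] objects (at least one).
#' @param spec a [colormap_spec()].
#' @return A `color_table`: data.frame with columns `temperature`, `r`,
#'   `g`, `b`, sorted by increasing temperature, rgb rows unique.
#' @export
build_color_table <- function(frames, spec = colormap_spec()) {
  if (inherits(frames, "thermal_frame")) frames <- list(frames)
  if (length(frames) == 0L) stop("need at least one frame", call. = FALSE)
  temps <- unlist(lapply(frames, function(f) as.vector(f$values)))
  temps <- pmin(spec$t_high, pmax(spec$t_low, temps))
  temps <- round(temps, 2)  # cents-of-degree resolution
  lev <- temperature_to_level(temps, spec)
  # exact duplicate (T, rgb) pairs collapse; distinct T sharing a level
  # average
  key <- paste(lev, temps)
  uni <- !duplicated(key)
  temps <- temps[uni]; lev <- lev[uni]
  mt <- tapply(temps, lev, mean)
  pal <- jet_palette(spec)
  idx <- as.integer(names(mt))
  tab <- data.frame(temperature = as.numeric(mt),
                    r = pal[idx, 1], g = pal[idx, 2], b = pal[idx, 3])
  tab <- tab[order(tab$temperature), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("color_table", "data.frame")
  tab
}

#' @export
print.color_table <- function(x, ...) {
  cat(sprintf("<color_table> %d rows, %.2f..%.2f degC\n", nrow(x),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Write / read a colour table as CSV
#' @param table a `color_table`.
#' @param path CSV path.
#' @export
write_color_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_color_table
#' @export
read_color_table <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("temperature", "r", "g", "b") %in% names(tab)))
  class(tab) <- c("color_table", "data.frame")
  tab
}
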