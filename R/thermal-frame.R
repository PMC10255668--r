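#' Thermal frames: the raster unit of the workflow
#'
#' A `thermal_frame` wraps one 240 x 320 matrix of skin temperatures in
#' degrees Celsius as exported in table form by an infrared camera, together
#' with a view label and optional acquisition metadata. Row 1 is the top of
#' the image and column 1 the left (image convention).
#'
#' @param values numeric matrix, exactly 240 rows x 320 columns, all finite
#'   and within the sensor range \[-20, 120\] degC.
#' @param view_id character scalar labelling the view (e.g. `"anterior"`,
#'   `"45deg_1"`).
#' @param timestamp optional ISO-8601 timestamp string.
#' @param metadata optional [acquisition_metadata()] record.
#' @return An object of class `thermal_frame`.
#' @seealso [read_thermal_frame()], [write_thermal_frame()]
#' @export
thermal_frame <- function(values, view_id = "unknown", timestamp = NULL,
                          metadata = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  validate_frame_values(values)
  structure(
    list(values = values, view_id = as.character(view_id)[1],
         timestamp = timestamp, metadata = metadata),
    class = "thermal_frame")
}

FRAME_ROWS <- 240L
FRAME_COLS <- 320L
SENSOR_RANGE <- c(-20, 120)

validate_frame_values <- function(values) {
  if (nrow(values) != FRAME_ROWS || ncol(values) != FRAME_COLS)
    stop(sprintf(
      "thermal frame must be %d x %d, got %d x %d",
      FRAME_ROWS, FRAME_COLS, nrow(values), ncol(values)), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("thermal frame contains non-finite values", call. = FALSE)
  rng <- range(values)
  if (rng[1] < SENSOR_RANGE[1] || rng[2] > SENSOR_RANGE[2])
    stop(sprintf(
      "temperatures [%.2f, %.2f] degC outside sensor range [%g, %g] degC",
      rng[1], rng[2], SENSOR_RANGE[1], SENSOR_RANGE[2]), call. = FALSE)
  invisible(values)
}

#' @export
print.thermal_frame <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<thermal_frame> view '%s', %d x %d, %.2f..%.2f degC\n",
              x$view_id, nrow(x$values), ncol(x$values), rng[1], rng[2]))
  invisible(x)
}

#' Acquisition metadata record
#'
#' Ambient conditions and protocol parameters recorded alongside each frame.
#' These are stored and propagated but never enter the computation: the
#' camera exports calibrated temperatures, so emissivity and ambient values
#' are documentation of the acquisition, not inputs to it.
#'
#' @param ambient_temperature ambient air temperature, degC (default 23).
#' @param relative_humidity relative humidity, percent (default 58.5).
#' @param emissivity skin emissivity used on the camera, in (0, 1\]
#'   (default 0.98, the standard value for human skin).
#' @param camera_distance camera-to-rotation-axis distance, cm (default 120).
#' @param condition_label `"rest"` or `"post_walk"`.
#' @param rest_minutes,walk_minutes protocol durations in minutes
#'   (record-only; defaults 20 and 15).
#' @return A list of class `acquisition_metadata`.
#' @export
acquisition_metadata <- function(ambient_temperature = 23,
                                 relative_humidity = 58.5,
                                 emissivity = 0.98,
                                 camera_distance = 120,
                                 condition_label = c("rest", "post_walk"),
                                 rest_minutes = 20, walk_minutes = 15) {
  condition_label <- match.arg(condition_label)
  stopifnot(emissivity > 0, emissivity <= 1, camera_distance > 0)
  structure(
    list(ambient_temperature = ambient_temperature,
         relative_humidity = relative_humidity,
         emissivity = emissivity,
         camera_distance = camera_distance,
         condition_label = condition_label,
         rest_minutes = rest_minutes,
         walk_minutes = walk_minutes),
    class = "acquisition_metadata")
}

detect_delimiter <- function(line) {
  # FLIR exports vary: semicolon + decimal comma is common in Europe, so a
  # comma is only taken as the separator when no semicolon/tab is present.
  for (sep in c(";", "\t", ","))
    if (grepl(sep, line, fixed = TRUE)) return(sep)
  " "
}

#' Read a thermal raster exported from the camera
#'
#' Reads one delimited numeric table of temperatures (comma, semicolon or
#' tab separated; decimal comma accepted) and validates it as a
#' [thermal_frame()]. If a JSON sidecar `<path>.json` exists its fields
#' (view_id, timestamp, acquisition metadata) are attached.
#'
#' @param path path to the delimited table.
#' @param view_id view label; when `NULL`, taken from the sidecar or the
#'   file name.
#' @return A validated [thermal_frame()].
#' @export
read_thermal_frame <- function(path, view_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- detect_delimiter(lines[1])
  dec <- "."
  if (sep != "," && any(grepl(",", lines[1], fixed = TRUE))) dec <- ","
  cells <- if (sep == " ") strsplit(trimws(lines), "[ ]+")
           else strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged table in %s: rows have %s columns", path,
                 paste(unique(ncols), collapse = "/")), call. = FALSE)
  flat <- trimws(unlist(cells))
  if (dec == ",") flat <- gsub(",", ".", flat, fixed = TRUE)
  num <- suppressWarnings(as.numeric(flat))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1]
    r <- (bad - 1L) %/% ncols[1] + 1L
    c <- (bad - 1L) %% ncols[1] + 1L
    stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                 flat[bad], r, c, path), call. = FALSE)
  }
  values <- matrix(num, nrow = length(lines), ncol = ncols[1], byrow = TRUE)

  sidecar <- paste0(path, ".json")
  meta <- NULL; ts <- NULL
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(view_id) && !is.null(sc$view_id)) view_id <- sc$view_id
    ts <- sc$timestamp
    known <- intersect(names(sc), names(formals(acquisition_metadata)))
    if (length(known)) meta <- do.call(acquisition_metadata, sc[known])
  }
  if (is.null(view_id))
    view_id <- tools::file_path_sans_ext(basename(path))
  thermal_frame(values, view_id = view_id, timestamp = ts, metadata = meta)
}

#' Write a thermal frame and its metadata sidecar
#'
#' Writes the temperature matrix as a comma-separated table (period decimal
#' mark, enough digits that a read round-trip reproduces values to 1e-6
#' degC) plus a JSON sidecar `<path>.json` with the view label, timestamp
#' and acquisition metadata.
#'
#' @param frame a [thermal_frame()].
#' @param path output path for the delimited table.
#' @return `path`, invisibly.
#' @export
write_thermal_frame <- function(frame, path) {
  stopifnot(inherits(frame, "thermal_frame"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  txt <- apply(frame$values, 1L, function(row)
    paste(formatC(row, format = "g", digits = 10), collapse = ","))
  ok <- tryCatch({writeLines(txt, path); TRUE},
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  sc <- list(view_id = frame$view_id)
  if (!is.null(frame$timestamp)) sc$timestamp <- frame$timestamp
  if (!is.null(frame$metadata)) sc <- c(sc, unclass(frame$metadata))
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
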