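#' Triangle mesh of the residual limb
#'
#' A light-weight triangle-mesh container: vertices in metres, 1-based
#' face indices, unit vertex normals, and optional per-vertex 8-bit rgb
#' colours and temperatures. The sentinel colour (0,0,0) marks vertices
#' that received no texture and whose temperature is `NA`.
#'
#' @param vertices n x 3 numeric matrix, metres.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 unit normals; computed (area-weighted,
#'   outward per face winding) when missing.
#' @param vertex_rgb optional n x 3 integer matrix, 0..255.
#' @param vertex_temperature optional numeric vector, degC (NA allowed for
#'   untextured vertices).
#' @param marker_vertex optional logical vector flagging fiducial-cube
#'   vertices.
#' @return An object of class `limb_mesh`.
#' @export
limb_mesh <- function(vertices, faces, normals = NULL, vertex_rgb = NULL,
                      vertex_temperature = NULL, marker_vertex = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (is.null(normals)) normals <- compute_vertex_normals(vertices, faces)
  m <- structure(
    list(vertices = vertices, faces = faces, normals = normals,
         vertex_rgb = vertex_rgb,
         vertex_temperature = vertex_temperature,
         marker_vertex = marker_vertex),
    class = "limb_mesh")
  m
}

#' @export
print.limb_mesh <- function(x, ...) {
  cat(sprintf("<limb_mesh> %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$vertex_rgb)) ", rgb" else "",
              if (!is.null(x$vertex_temperature)) ", temperature" else ""))
  invisible(x)
}

#' Area-weighted vertex normals
#' @param vertices n x 3 matrix; `faces` m x 3 1-based indices.
#' @return n x 3 matrix of unit normals (zero rows for isolated vertices).
#' @export
compute_vertex_normals <- function(vertices, faces) {
  n <- nrow(vertices)
  if (nrow(faces) == 0) return(matrix(0, n, 3))
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  acc <- matrix(0, n, 3)
  for (k in 1:3) {
    s <- rowsum(rbind(fn, fn, fn)[, k],
                group = c(faces[, 1], faces[, 2], faces[, 3]))
    acc[as.integer(rownames(s)), k] <- s
  }
  len <- sqrt(rowSums(acc^2))
  len[len < 1e-20] <- 1
  acc / len
}

face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(fn^2))
}

vertex_adjacency_graph <- function(mesh) {
  ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  igraph::graph_from_edgelist(ed, directed = FALSE)
}

#' Clean and decimate a raw surface scan
#'
#' Reproduces the scan post-processing: keep the largest connected
#' component, drop interior vertices (those from which no axis-aligned ray
#' escapes the mesh unoccluded — debris inside the surface), then quadric
#' edge-collapse decimation to the target vertex count (within 10%; a mesh
#' already at or below the target is returned unchanged).
#'
#' @param mesh a [limb_mesh()].
#' @param target_vertices target vertex count (default 16000, the working
#'   resolution of the limb model).
#' @param remove_interior run the interior-vertex test (default TRUE).
#' @return A cleaned [limb_mesh()].
#' @export
clean_mesh <- function(mesh, target_vertices = 16000L,
                       remove_interior = TRUE) {
  stopifnot(inherits(mesh, "limb_mesh"))
  if (nrow(mesh$vertices) == 0) stop("empty mesh", call. = FALSE)
  # largest connected component
  g <- vertex_adjacency_graph(mesh)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    keep <- which(comp$membership == which.max(comp$csize))
    mesh <- subset_mesh(mesh, keep)
  }
  if (remove_interior && nrow(mesh$vertices) > 0) {
    ext <- exterior_vertices(mesh)
    if (!all(ext) && any(ext)) mesh <- subset_mesh(mesh, which(ext))
  }
  if (nrow(mesh$vertices) == 0) stop("cleaning removed all vertices",
                                     call. = FALSE)
  if (nrow(mesh$vertices) > target_vertices) {
    d <- decimate_mesh_cpp(mesh$vertices, mesh$faces,
                           as.integer(target_vertices))
    mesh <- limb_mesh(d$vertices, d$faces)
  }
  mesh
}

subset_mesh <- function(mesh, keep) {
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  fk <- mesh$faces[rowSums(matrix(mesh$faces %in% keep,
                                  ncol = 3)) == 3L, , drop = FALSE]
  fk <- matrix(map[fk], ncol = 3)
  limb_mesh(mesh$vertices[keep, , drop = FALSE], fk,
            vertex_rgb = if (!is.null(mesh$vertex_rgb))
              mesh$vertex_rgb[keep, , drop = FALSE],
            vertex_temperature = mesh$vertex_temperature[keep],
            marker_vertex = mesh$marker_vertex[keep])
}

# A vertex is exterior when at least one of the six axis rays from it
# leaves the mesh without hitting other geometry.
exterior_vertices <- function(mesh) {
  n <- nrow(mesh$vertices)
  diam <- sqrt(sum((apply(mesh$vertices, 2, max) -
                      apply(mesh$vertices, 2, min))^2)) + 1
  ext <- rep(FALSE, n)
  # six spread directions, deliberately off the coordinate axes: exact
  # axis rays can thread through shared vertices of axis-symmetric
  # meshes without registering a hit
  dirs <- rbind(c(1, 0.31, 0.17), c(-1, -0.23, 0.29), c(0.27, 1, -0.19),
                c(-0.33, -1, -0.13), c(0.21, -0.37, 1), c(-0.17, 0.25, -1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (k in seq_len(nrow(dirs))) {
    open <- which(!ext)
    if (!length(open)) break
    d <- matrix(dirs[k, ], length(open), 3, byrow = TRUE)
    occ <- ray_occluded_cpp(mesh$vertices[open, , drop = FALSE], d,
                            rep(diam, length(open)),
                            mesh$vertices, mesh$faces, eps = 1e-5)
    ext[open[!occ]] <- TRUE
  }
  ext
}

# --- PLY I/O -----------------------------------------------------------------

#' Write a mesh as PLY
#'
#' Writes ASCII or binary little-endian PLY with per-vertex positions,
#' normals, optional uchar red/green/blue and optional float scalar
#' properties (`temperature`, `delta_t`, ...). Sentinel (untextured)
#' vertices keep colour (0,0,0) and serialise scalar values as NaN.
#'
#' @param mesh a [limb_mesh()].
#' @param path output path.
#' @param binary write `binary_little_endian` (default) or ASCII.
#' @param scalars named list of additional per-vertex float properties;
#'   `vertex_temperature` is written automatically as `temperature`.
#' @param comments character vector of header comment lines.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, binary = TRUE, scalars = list(),
                      comments = character()) {
  stopifnot(inherits(mesh, "limb_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  if (!is.null(mesh$vertex_temperature) &&
      is.null(scalars[["temperature"]]))
    scalars$temperature <- mesh$vertex_temperature
  has_rgb <- !is.null(mesh$vertex_rgb)

  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           paste("comment", c("produced by thermomap3d", comments)),
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           if (has_rgb) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           vapply(names(scalars), function(s)
             sprintf("property float %s", s), character(1)),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  fl <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                             endian = "little")
  if (binary) {
    # interleave per-vertex records as raw bytes: stack each property's
    # byte-matrix and write column-major
    chunks <- list(matrix(fl(t(cbind(mesh$vertices, mesh$normals))),
                          nrow = 24L))
    if (has_rgb)
      chunks <- c(chunks, list(matrix(as.raw(t(mesh$vertex_rgb)),
                                      nrow = 3L)))
    for (s in names(scalars))
      chunks <- c(chunks, list(matrix(fl(scalars[[s]]), nrow = 4L)))
    writeBin(as.vector(do.call(rbind, chunks)), con)
    fr <- rbind(matrix(as.raw(3L), 1L, nf),
                matrix(writeBin(as.integer(t(mesh$faces) - 1L), raw(),
                                size = 4, endian = "little"), nrow = 12L))
    writeBin(as.vector(fr), con)
  } else {
    vtab <- cbind(mesh$vertices, mesh$normals)
    cols <- apply(vtab, 1, function(r)
      paste(formatC(r, format = "g", digits = 8), collapse = " "))
    if (has_rgb)
      cols <- paste(cols, apply(mesh$vertex_rgb, 1, paste, collapse = " "))
    for (s in names(scalars)) {
      v <- ifelse(is.na(scalars[[s]]), "nan",
                  formatC(scalars[[s]], format = "g", digits = 8))
      cols <- paste(cols, v)
    }
    writeLines(cols, con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Reads ASCII or binary little-endian PLY files with float/double/uchar/
#' int vertex properties and triangular faces, reconstructing positions,
#' normals, colours and any float scalar properties (returned in
#' `$scalars`; a `temperature` property populates `vertex_temperature`).
#'
#' @param path PLY path.
#' @return A [limb_mesh()]; extra scalar properties in `$scalars`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) stop("unterminated PLY header", call. = FALSE)
    hdr <- c(hdr, l)
    if (l == "end_header") break
  }
  if (hdr[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  fmt <- strsplit(hdr[grepl("^format ", hdr)][1], " ")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt, call. = FALSE)

  # parse element/property layout
  elements <- list(); cur <- NULL
  for (l in hdr) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]),
                              props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        elements[[cur]]$props <- c(elements[[cur]]$props,
                                   list(list(name = tok[5], list = TRUE,
                                             count_type = tok[3],
                                             type = tok[4])))
      else
        elements[[cur]]$props <- c(elements[[cur]]$props,
                                   list(list(name = tok[3], list = FALSE,
                                             type = tok[2])))
    }
  }
  tsize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)

  ve <- elements[["vertex"]]; fe <- elements[["face"]]
  if (is.null(ve)) stop("PLY without vertex element", call. = FALSE)
  nv <- ve$count; nf <- if (is.null(fe)) 0L else fe$count

  if (fmt == "ascii") {
    lines <- readLines(con)
    vcells <- strsplit(trimws(lines[seq_len(nv)]), "\\s+")
    vdat <- matrix(suppressWarnings(
      as.numeric(unlist(vcells))), nrow = nv, byrow = TRUE)
    colnames(vdat) <- vapply(ve$props, `[[`, "", "name")
    if (nf > 0) {
      fcells <- strsplit(trimws(lines[nv + seq_len(nf)]), "\\s+")
      fdat <- t(vapply(fcells, function(x) as.integer(x[2:4]), integer(3)))
    } else fdat <- matrix(integer(), 0, 3)
  } else {
    sizes <- vapply(ve$props, function(p) tsize[[p$type]], integer(1))
    rec <- sum(sizes)
    blob <- readBin(con, "raw", n = rec * nv)
    offs <- cumsum(c(0L, sizes))
    vdat <- matrix(NA_real_, nv, length(ve$props))
    colnames(vdat) <- vapply(ve$props, `[[`, "", "name")
    base <- rep((seq_len(nv) - 1L) * rec, each = 1L)
    for (j in seq_along(ve$props)) {
      p <- ve$props[[j]]; sz <- sizes[j]
      pick <- as.vector(outer(seq_len(sz), base + offs[j], "+"))
      bytes <- blob[pick]
      vdat[, j] <- switch(p$type,
        float = , float32 = readBin(bytes, "numeric", n = nv, size = 4,
                                    endian = "little"),
        double = , float64 = readBin(bytes, "numeric", n = nv, size = 8,
                                     endian = "little"),
        uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = nv,
                                             size = 1, signed = FALSE)),
        char = , int8 = as.numeric(readBin(bytes, "integer", n = nv,
                                           size = 1, signed = TRUE)),
        int = , int32 = , uint = , uint32 =
          as.numeric(readBin(bytes, "integer", n = nv, size = 4,
                             endian = "little")),
        stop("unsupported vertex property type: ", p$type, call. = FALSE))
    }
    if (nf > 0) {
      # assume triangles: uchar count + 3 ints (the writer's layout)
      fblob <- readBin(con, "raw", n = 13L * nf)
      counts <- as.integer(fblob[(seq_len(nf) - 1L) * 13L + 1L])
      if (any(counts != 3L))
        stop("non-triangular PLY faces are not supported", call. = FALSE)
      pick <- as.vector(outer(2:13, (seq_len(nf) - 1L) * 13L, "+"))
      fdat <- matrix(readBin(fblob[pick], "integer", n = 3L * nf, size = 4,
                             endian = "little"), ncol = 3, byrow = TRUE)
    } else fdat <- matrix(integer(), 0, 3)
  }

  nm <- colnames(vdat)
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% nm))
    vdat[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  rgb <- if (all(c("red", "green", "blue") %in% nm))
    matrix(as.integer(vdat[, c("red", "green", "blue")]), ncol = 3)
  else NULL
  std <- c("x", "y", "z", "nx", "ny", "nz", "red", "green", "blue")
  scalars <- lapply(setdiff(nm, std), function(s) vdat[, s])
  names(scalars) <- setdiff(nm, std)
  temp <- scalars[["temperature"]]
  if (!is.null(temp)) temp[is.nan(temp)] <- NA_real_
  m <- limb_mesh(verts, fdat + 1L, normals = normals, vertex_rgb = rgb,
                 vertex_temperature = temp)
  m$scalars <- scalars
  m
}
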