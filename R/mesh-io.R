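#' Triangulated surface mesh
#'
#' Constructs a validated `surface_mesh`: an oriented triangulated surface
#' in instrument coordinates (millimetres, right-handed, origin at the
#' calibration chessboard center, z up). Absent vertex normals are computed
#' as area-weighted averages of incident facet normals.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param normals optional numeric n x 3 matrix of outward unit vertex
#'   normals; computed from the facets when `NULL`.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `normals`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stopf("faces must be an m x 3 matrix")
  if (nrow(faces) < 1L) stopf("mesh has zero facets")
  if (anyNA(vertices) || anyNA(faces)) stopf("mesh contains missing values")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stopf("facet references an invalid vertex index")
  if (is.null(normals)) {
    normals <- compute_vertex_normals(vertices, faces)
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(vertices)))
      stopf("normals must match vertices in dimension")
    len <- row_norms(normals)
    if (any(len < 1e-12)) stopf("zero-length vertex normal")
    normals <- normals / len
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  dimnames(normals) <- NULL
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d facets\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Facet normals scaled by twice the facet area (cross product magnitude),
# so that summing per-vertex weights by area.
facet_normals_raw <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

compute_vertex_normals <- function(vertices, faces) {
  fn <- facet_normals_raw(vertices, faces)
  n <- matrix(0, nrow(vertices), 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], group = faces[, j], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      n[idx, k] <- n[idx, k] + acc[, 1]
    }
  }
  len <- row_norms(n)
  # vertices not referenced by any facet get an arbitrary vertical normal
  bad <- len < 1e-12
  n[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
  len[bad] <- 1
  n / len
}

#' Read a triangulated mesh from PLY, OBJ or STL
#'
#' Supports ASCII and binary-little-endian PLY, Wavefront OBJ (`v`/`vn`/`f`
#' records, polygonal faces fan-triangulated) and ASCII or binary STL
#' (duplicate facet vertices are merged). Normals absent from the file are
#' computed from the facets.
#'
#' @param path file path; format inferred from the extension.
#' @return A [surface_mesh].
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  if (file.size(path) == 0) stopf("mesh file is empty: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path),
         stopf("unsupported mesh format: .%s", ext))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stopf("truncated PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 200L) stopf("malformed PLY header")
  }
  if (trimws(header[1]) != "ply") stopf("not a PLY file: %s", path)
  fmt_line <- grep("^format", trimws(header), value = TRUE)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stopf("unsupported PLY format: %s", fmt)

  # parse element/property declarations
  elems <- list()
  cur <- NULL
  for (line in trimws(header)) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face))
    stopf("PLY file lacks vertex or face element")

  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    nv <- elems$vertex$count
    nf <- elems$face$count
    if (length(body) < nv + nf) stopf("truncated PLY body")
    vprops <- vapply(elems$vertex$props, `[[`, "", "name")
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
                   nrow = nv, byrow = TRUE)
    colnames(vdat) <- vprops[seq_len(ncol(vdat))]
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(fl, function(t) {
      n <- as.integer(t[1])
      if (n != 3L) stopf("only triangular PLY faces are supported")
      as.integer(t[2:4]) + 1L
    }))
  } else {
    nv <- elems$vertex$count
    vp <- elems$vertex$props
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
               int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L)
    read_scalar <- function(type, n) {
      sz <- sizes[[type]]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(con, "double", n = n, size = sz, endian = "little")
      else
        readBin(con, "integer", n = n, size = sz, endian = "little",
                signed = !grepl("^u", type))
    }
    vdat <- matrix(0, nv, length(vp))
    colnames(vdat) <- vapply(vp, `[[`, "", "name")
    # vertices are homogeneous scalar records; read interleaved
    types <- vapply(vp, `[[`, "", "type")
    if (length(unique(types)) == 1L) {
      raw <- read_scalar(types[1], nv * length(vp))
      vdat[] <- matrix(raw, nv, length(vp), byrow = TRUE)
    } else {
      for (i in seq_len(nv))
        for (j in seq_along(vp)) vdat[i, j] <- read_scalar(types[j], 1L)
    }
    nf <- elems$face$count
    fp <- elems$face$props[[1]]
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- read_scalar(fp$count_type, 1L)
      if (cnt != 3L) stopf("only triangular PLY faces are supported")
      faces[i, ] <- as.integer(read_scalar(fp$type, 3L)) + 1L
    }
  }
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% colnames(vdat)))
    vdat[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  surface_mesh(verts, faces, normals)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L || length(fl) == 0L) stopf("OBJ file lacks vertices or faces")
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t)
    as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t) {
    idx <- as.integer(vapply(strsplit(t[-1], "/"), `[[`, "", 1L))
    if (length(idx) < 3L) stopf("OBJ face with fewer than 3 vertices")
    # fan-triangulate polygons
    cbind(idx[1], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }))
  surface_mesh(verts, faces)
}

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 facet count + 50 bytes per facet
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = 80L)
  nfac <- tryCatch(readBin(con, "integer", size = 4L, endian = "little"),
                   error = function(e) NA_integer_)
  is_binary <- !is.na(nfac) && sz == 84 + 50 * as.numeric(nfac)
  if (is_binary) {
    tri <- matrix(0, nfac * 3L, 3L)
    for (i in seq_len(nfac)) {
      rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      tri[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3L, byrow = TRUE)
      readBin(con, "raw", n = 2L)
    }
    close(con)
  } else {
    close(con)
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "vertex")]
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stopf("malformed ASCII STL: %s", path)
    tri <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t)
      as.numeric(t[2:4])))
  }
  # merge duplicated vertices (STL stores each facet independently)
  key <- apply(round(tri, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write a mesh to PLY, OBJ or STL
#'
#' @param mesh a [surface_mesh].
#' @param path output path; format inferred from the extension.
#' @param binary write binary-little-endian PLY instead of ASCII
#'   (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces; n <- mesh$normals
  if (ext == "ply") {
    header <- c("ply",
                sprintf("format %s 1.0",
                        if (binary) "binary_little_endian" else "ascii"),
                sprintf("element vertex %d", nrow(v)),
                "property double x", "property double y", "property double z",
                "property double nx", "property double ny", "property double nz",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices",
                "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(header, con)
      writeBin(as.vector(t(cbind(v, n))), con, size = 8L, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      }
    } else {
      body <- apply(cbind(v, n), 1, paste, collapse = " ")
      fb <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
      writeLines(c(header, body, fb), path)
    }
  } else if (ext == "obj") {
    writeLines(c(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]),
                 sprintf("vn %.12g %.12g %.12g", n[, 1], n[, 2], n[, 3]),
                 sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  } else if (ext == "stl") {
    fn <- facet_normals_raw(v, f)
    len <- pmax(row_norms(fn), 1e-300)
    fn <- fn / len
    out <- c("solid musescan")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      out <- c(out,
               sprintf("facet normal %.12g %.12g %.12g", fn[i, 1], fn[i, 2], fn[i, 3]),
               "outer loop",
               sprintf("vertex %.12g %.12g %.12g", tri[, 1], tri[, 2], tri[, 3]),
               "endloop", "endfacet")
    }
    writeLines(c(out, "endsolid musescan"), path)
  } else stopf("unsupported mesh format: .%s", ext)
  invisible(path)
}

#' Mesh validation report
#'
#' Summary statistics used by the command-line tools; serializable to JSON.
#'
#' @param mesh a [surface_mesh].
#' @return A list: vertex/facet counts, bounding box, total area, normal
#'   unit-length check, and count of unreferenced vertices.
#' @export
mesh_validation_report <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  fn <- facet_normals_raw(mesh$vertices, mesh$faces)
  areas <- row_norms(fn) / 2
  used <- seq_len(nrow(mesh$vertices)) %in% as.vector(mesh$faces)
  list(n_vertices = nrow(mesh$vertices),
       n_facets = nrow(mesh$faces),
       bbox_mm = apply(mesh$vertices, 2, range),
       total_area_mm2 = sum(areas),
       normals_unit = max(abs(row_norms(mesh$normals) - 1)) < 1e-9,
       n_unreferenced_vertices = sum(!used),
       n_degenerate_facets = sum(areas < 1e-12))
}
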