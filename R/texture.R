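# Textured-surface assembly, rasterization and export.

bilinear_sample <- function(img, px) {
  # px: n x 2 (x = column, y = row), 0-based pixel coordinates
  x <- clamp(px[, 1], 0, ncol(img) - 1)
  y <- clamp(px[, 2], 0, nrow(img) - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, ncol(img) - 1); y1 <- pmin(y0 + 1, nrow(img) - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- img[cbind(y0 + 1, x0 + 1)]; v01 <- img[cbind(y0 + 1, x1 + 1)]
  v10 <- img[cbind(y1 + 1, x0 + 1)]; v11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Assemble a textured surface
#'
#' Binds a mesh, the fused tiles, their projections and the view-
#' selection labels into one object. Facets with differing labels across
#' a shared edge form the seam set.
#'
#' @param mesh a [surface_mesh].
#' @param tiles list of `fused_tile` (or matrices), indexed by tile id.
#' @param projections list of [project_tile] results, aligned with
#'   `tiles`.
#' @param labels integer tile id per facet (NA = unassigned), as from
#'   [select_views].
#' @return A `textured_surface`.
#' @export
texture_surface <- function(mesh, tiles, projections, labels) {
  nf <- nrow(mesh$faces)
  if (length(labels) != nf) stopf("labels must align with facets")
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  sp <- split(rep(seq_len(nf), 3L), ekey)
  seams <- list()
  for (grp in sp) {
    if (length(grp) == 2L && !anyNA(labels[grp]) &&
        labels[grp[1]] != labels[grp[2]])
      seams[[length(seams) + 1L]] <- grp
  }
  structure(list(mesh = mesh, tiles = tiles, projections = projections,
                 facet_view = labels, seam_facets = seams),
            class = "textured_surface")
}

#' Top-down raster of a textured surface
#'
#' Orthographic rasterization onto the x-y plane: each assigned facet is
#' filled by barycentric interpolation of its vertex texture coordinates
#' and bilinear sampling of its tile. Used to compare the synthesized
#' texture against ground truth on height-field fixtures.
#'
#' @param ts a `textured_surface`.
#' @param px_per_mm raster resolution.
#' @return List: `image` (matrix, NA where uncovered), `x0`, `y0`,
#'   `px_per_mm` (raster origin and scale).
#' @export
rasterize_texture <- function(ts, px_per_mm = 20) {
  mesh <- ts$mesh
  v <- mesh$vertices; f <- mesh$faces
  bb <- apply(v[, 1:2, drop = FALSE], 2, range)
  nx <- ceiling((bb[2, 1] - bb[1, 1]) * px_per_mm) + 1L
  ny <- ceiling((bb[2, 2] - bb[1, 2]) * px_per_mm) + 1L
  out <- matrix(NA_real_, ny, nx)
  for (i in seq_len(nrow(f))) {
    tid <- ts$facet_view[i]
    if (is.na(tid)) next
    uvm <- ts$projections[[tid]]$uv[[i]]
    if (is.null(uvm)) next
    tri <- v[f[i, ], 1:2, drop = FALSE]
    cx <- (tri[, 1] - bb[1, 1]) * px_per_mm + 1
    cy <- (tri[, 2] - bb[1, 2]) * px_per_mm + 1
    xr <- max(1L, floor(min(cx))):min(nx, ceiling(max(cx)))
    yr <- max(1L, floor(min(cy))):min(ny, ceiling(max(cy)))
    if (length(xr) == 0L || length(yr) == 0L) next
    gp <- expand.grid(x = xr, y = yr)
    # barycentric coordinates in the 2D projection
    d <- (cy[2] - cy[3]) * (cx[1] - cx[3]) + (cx[3] - cx[2]) * (cy[1] - cy[3])
    if (abs(d) < 1e-12) next
    w1 <- ((cy[2] - cy[3]) * (gp$x - cx[3]) + (cx[3] - cx[2]) * (gp$y - cy[3])) / d
    w2 <- ((cy[3] - cy[1]) * (gp$x - cx[3]) + (cx[1] - cx[3]) * (gp$y - cy[3])) / d
    w3 <- 1 - w1 - w2
    inside <- w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9
    if (!any(inside)) next
    px <- cbind(w1, w2, w3)[inside, , drop = FALSE] %*% uvm
    img <- ts$tiles[[tid]]
    if (inherits(img, "fused_tile")) img <- img$image
    vals <- bilinear_sample(img, px)
    out[cbind(gp$y[inside], gp$x[inside])] <- vals
  }
  list(image = out, x0 = bb[1, 1], y0 = bb[1, 2], px_per_mm = px_per_mm)
}

#' Export a textured surface as OBJ + MTL + PNG atlas
#'
#' Tiles are packed into a horizontal strip atlas; facet vertex texture
#' coordinates are remapped into the packed regions.
#'
#' @param ts a `textured_surface`.
#' @param path_prefix output prefix; writes `<prefix>.obj`,
#'   `<prefix>.mtl`, `<prefix>.png`.
#' @return The OBJ path, invisibly.
#' @export
write_textured_surface <- function(ts, path_prefix) {
  tiles <- lapply(ts$tiles, function(t) if (inherits(t, "fused_tile")) t$image else t)
  th <- max(vapply(tiles, nrow, integer(1)))
  tw <- vapply(tiles, ncol, integer(1))
  atlas <- matrix(0, th, sum(tw))
  xoff <- cumsum(c(0, head(tw, -1)))
  for (k in seq_along(tiles))
    atlas[seq_len(nrow(tiles[[k]])), xoff[k] + seq_len(tw[k])] <- tiles[[k]]
  png::writePNG(clamp(atlas / 255, 0, 1), paste0(path_prefix, ".png"))

  v <- ts$mesh$vertices; f <- ts$mesh$faces
  obj <- c(sprintf("mtllib %s.mtl", basename(path_prefix)),
           sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
           "usemtl atlas")
  vt_lines <- character(0)
  face_lines <- character(0)
  vt_count <- 0L
  for (i in seq_len(nrow(f))) {
    tid <- ts$facet_view[i]
    if (is.na(tid) || is.null(ts$projections[[tid]]$uv[[i]])) next
    uvm <- ts$projections[[tid]]$uv[[i]]
    un <- (uvm[, 1] + xoff[tid]) / sum(tw)
    vn <- 1 - uvm[, 2] / th
    vt_lines <- c(vt_lines, sprintf("vt %.6f %.6f", un, vn))
    face_lines <- c(face_lines, sprintf("f %d/%d %d/%d %d/%d",
                                        f[i, 1], vt_count + 1L,
                                        f[i, 2], vt_count + 2L,
                                        f[i, 3], vt_count + 3L))
    vt_count <- vt_count + 3L
  }
  writeLines(c(obj, vt_lines, face_lines), paste0(path_prefix, ".obj"))
  writeLines(c("newmtl atlas", "Ka 1 1 1", "Kd 1 1 1",
               sprintf("map_Kd %s.png", basename(path_prefix))),
             paste0(path_prefix, ".mtl"))
  invisible(paste0(path_prefix, ".obj"))
}
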