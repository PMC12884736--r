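# Mesh cleaning, centroid/normal estimation, and closest-point queries.
# All positions in mm, instrument frame.

#' Surface point
#'
#' A position constrained to lie on a mesh surface together with the
#' outward unit normal there.
#'
#' @param position numeric length-3 (mm).
#' @param normal numeric length-3 unit vector.
#' @return An object of class `surface_point`.
#' @export
surface_point <- function(position, normal) {
  structure(list(position = as.numeric(position),
                 normal = normalize(as.numeric(normal))),
            class = "surface_point")
}

#' @export
print.surface_point <- function(x, ...) {
  cat(sprintf("surface_point (%.4f, %.4f, %.4f) mm, n = (%.3f, %.3f, %.3f)\n",
              x$position[1], x$position[2], x$position[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# Closest points on a set of triangles (A, B, C: m x 3) to a single point p.
# Vectorized version of the standard barycentric-region algorithm.
closest_point_triangles <- function(p, A, B, C) {
  m <- nrow(A)
  ab <- B - A; ac <- C - A
  ap <- matrix(p, m, 3, byrow = TRUE) - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, m, 3, byrow = TRUE) - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, m, 3, byrow = TRUE) - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  out <- matrix(NA_real_, m, 3)
  done <- rep(FALSE, m)
  set <- function(mask, pts) {
    mask <- mask & !done
    out[mask, ] <<- pts[mask, , drop = FALSE]
    done[mask] <<- TRUE
  }
  set(d1 <= 0 & d2 <= 0, A)                                  # vertex A
  set(d3 >= 0 & d4 <= d3, B)                                 # vertex B
  t_ab <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * t_ab)            # edge AB
  set(d6 >= 0 & d5 <= d6, C)                                 # vertex C
  t_ac <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * t_ac)            # edge AC
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * t_bc) # edge BC
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  set(!done, A + ab * v + ac * w)                            # interior
  out
}

#' Closest point on a mesh surface
#'
#' @param mesh a [surface_mesh].
#' @param point numeric length-3 query position (mm).
#' @return A list with `position` (closest surface point), `facet`
#'   (1-based facet index) and `distance` (mm).
#' @export
closest_point_on_mesh <- function(mesh, point) {
  v <- mesh$vertices; f <- mesh$faces
  cp <- closest_point_triangles(as.numeric(point),
                                v[f[, 1], , drop = FALSE],
                                v[f[, 2], , drop = FALSE],
                                v[f[, 3], , drop = FALSE])
  d2 <- rowSums((cp - matrix(as.numeric(point), nrow(cp), 3, byrow = TRUE))^2)
  i <- which.min(d2)
  list(position = cp[i, ], facet = i, distance = sqrt(d2[i]))
}

# Outward unit normal of facet i, oriented to agree with its vertex normals.
facet_unit_normal <- function(mesh, i) {
  fn <- facet_normals_raw(mesh$vertices, mesh$faces[i, , drop = FALSE])[1, ]
  fn <- normalize(fn)
  ref <- colMeans(mesh$normals[mesh$faces[i, ], , drop = FALSE])
  if (sum(fn * ref) < 0) fn <- -fn
  fn
}

# Nearest-neighbor distances between rows of X, chunked to bound memory.
nn_distances <- function(X, chunk = 2000L) {
  n <- nrow(X)
  out <- numeric(n)
  sq <- rowSums(X^2)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * X[idx, , drop = FALSE] %*% t(X)
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# Indices of the k nearest rows of X to point p.
knn_indices <- function(X, p, k) {
  d2 <- rowSums((X - matrix(p, nrow(X), ncol(X), byrow = TRUE))^2)
  order(d2)[seq_len(k)]
}

#' Clean a surface mesh
#'
#' Removes isolated vertices (no other vertex within `isolation_radius`)
#' and applies uniform-weight Laplacian smoothing with relaxation factor
#' 0.5. Facets referencing removed vertices are dropped and indices
#' re-packed.
#'
#' @param mesh a [surface_mesh].
#' @param smoothing_iters number of Laplacian smoothing sweeps (>= 0).
#' @param isolation_radius mm; vertices with no neighbor closer than this
#'   are removed. Default 2 mm.
#' @return A cleaned [surface_mesh].
#' @export
clean_mesh <- function(mesh, smoothing_iters = 0L, isolation_radius = 2) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (smoothing_iters < 0) stopf("smoothing_iters must be >= 0")
  v <- mesh$vertices; f <- mesh$faces
  keep <- nn_distances(v) <= isolation_radius
  if (!any(keep)) stopf("cleaning removed all vertices")
  remap <- cumsum(keep)
  fkeep <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  if (!any(fkeep)) stopf("cleaning removed all facets")
  v <- v[keep, , drop = FALSE]
  f <- matrix(remap[f[fkeep, ]], ncol = 3L)
  if (smoothing_iters > 0) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    edges <- rbind(edges, edges[, c(2, 1)])
    adj <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                                dims = c(nrow(v), nrow(v)))
    adj@x[] <- 1  # collapse duplicate edge entries to weight 1
    deg <- Matrix::rowSums(adj)
    deg[deg == 0] <- 1
    for (it in seq_len(smoothing_iters)) {
      avg <- as.matrix(adj %*% v) / deg
      v <- v + 0.5 * (avg - v)
    }
  }
  surface_mesh(v, f)
}

#' Area-weighted surface centroid
#'
#' The area-weighted average of facet centroids, snapped back to the
#' surface (the raw centroid of a curved mesh lies off-surface). The
#' snap projects the raw centroid onto the tangent plane at the nearest
#' mesh vertex: a first-order surface projection that respects mesh
#' symmetries (on a symmetric hemisphere it returns the apex exactly,
#' where a nearest-facet snap would land arbitrarily on one of many
#' tied chordal facets).
#'
#' @param mesh a [surface_mesh].
#' @return A [surface_point] on the mesh.
#' @export
mesh_centroid <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) stopf("empty mesh")
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  w <- row_norms(facet_normals_raw(v, f)) / 2
  if (sum(w) < 1e-15) stopf("mesh has zero total area")
  cen <- colSums(fc * w) / sum(w)
  vi <- knn_indices(v, cen, 1L)
  nv <- mesh$normals[vi, ]
  pos <- cen - sum((cen - v[vi, ]) * nv) * nv
  surface_point(pos, nv)
}

#' Local least-squares surface normal
#'
#' Fits a plane to the `k` mesh vertices nearest `point` (k-d-tree style
#' neighborhood query) and returns the plane normal, oriented to agree
#' with the mean vertex normal of the neighborhood.
#'
#' @param mesh a [surface_mesh].
#' @param point numeric length-3 (mm).
#' @param k neighbor count (>= 3).
#' @return Unit normal vector (length 3).
#' @export
local_normal <- function(mesh, point, k = 12L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (k < 3L) stopf("k must be >= 3")
  if (nrow(mesh$vertices) < k) stopf("mesh has fewer than k vertices")
  idx <- knn_indices(mesh$vertices, as.numeric(point), k)
  nb <- mesh$vertices[idx, , drop = FALSE]
  cen <- sweep(nb, 2, colMeans(nb))
  sv <- svd(cen)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stopf("degenerate (collinear) neighborhood for normal estimation")
  n <- sv$v[, 3]
  ref <- colMeans(mesh$normals[idx, , drop = FALSE])
  if (sum(n * ref) < 0) n <- -n
  normalize(n)
}
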