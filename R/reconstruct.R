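# Surface reconstruction from oriented point sets.
#
# Non-planar sets: an implicit signed-distance field (distance to the
# tangent plane of the nearest sample point, the classic oriented-point
# construction) is contoured at zero by marching tetrahedra on a regular
# grid. Planar sets fall back to a 2D Delaunay triangulation lifted back
# into the plane.

# ---- 2D Delaunay (Bowyer-Watson, incremental) -------------------------

circumcircle <- function(p1, p2, p3) {
  ax <- p1[, 1]; ay <- p1[, 2]
  bx <- p2[, 1]; by <- p2[, 2]
  cx <- p3[, 1]; cy <- p3[, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  cbind(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

delaunay2d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stopf("need at least 3 points to triangulate")
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  mid <- colMeans(rng)
  # enclosing super-triangle
  sup <- rbind(mid + c(-20 * span, -10 * span),
               mid + c(20 * span, -10 * span),
               mid + c(0, 20 * span))
  P <- rbind(pts, sup)
  tris <- matrix(n + 1:3, 1, 3)
  cc <- circumcircle(P[tris[, 1], , drop = FALSE],
                     P[tris[, 2], , drop = FALSE],
                     P[tris[, 3], , drop = FALSE])
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 < cc[, 3] * (1 + 1e-12)
    if (!any(bad)) {
      # numerically on a circumcircle boundary; nudge test
      bad <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3]
      if (!any(bad)) stopf("degenerate point configuration in triangulation")
    }
    hole <- tris[bad, , drop = FALSE]
    edges <- rbind(hole[, c(1, 2)], hole[, c(2, 3)], hole[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    newt <- cbind(boundary, i)
    tris <- rbind(tris[!bad, , drop = FALSE], newt)
    cc <- rbind(cc[!bad, , drop = FALSE],
                circumcircle(P[newt[, 1], , drop = FALSE],
                             P[newt[, 2], , drop = FALSE],
                             P[newt[, 3], , drop = FALSE]))
  }
  keep <- tris[, 1] <= n & tris[, 2] <= n & tris[, 3] <= n
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0L) stopf("triangulation failed (collinear points?)")
  tris
}

# ---- marching tetrahedra ----------------------------------------------

# 6-tetrahedra decomposition of the unit cube (corners 0..7, shared
# diagonal 0-6); corner k has offset (bit0, bit1, bit2) per `cube_off`.
.cube_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
.tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
               c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

march_tetrahedra <- function(F, xs, ys, zs) {
  G <- c(length(xs), length(ys), length(zs))
  dim(F) <- G
  ii <- seq_len(G[1] - 1L); jj <- seq_len(G[2] - 1L); kk <- seq_len(G[3] - 1L)
  cells <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  lin <- function(off) {
    (cells[, 1] + off[1]) + (cells[, 2] + off[2] - 1L) * G[1] +
      (cells[, 3] + off[3] - 1L) * G[1] * G[2]
  }
  corner_idx <- sapply(seq_len(8), function(k) lin(.cube_off[k, ]))
  coord <- function(idx) {
    idx0 <- idx - 1L
    i <- idx0 %% G[1] + 1L
    j <- (idx0 %/% G[1]) %% G[2] + 1L
    k <- idx0 %/% (G[1] * G[2]) + 1L
    cbind(xs[i], ys[j], zs[k])
  }
  tri_pts <- vector("list", 64L)
  nt <- 0L
  interp <- function(i1, i2) {
    a <- F[i1]; b <- F[i2]
    t <- a / (a - b)
    coord(i1) + t * (coord(i2) - coord(i1))
  }
  for (tt in seq_len(6)) {
    vi <- corner_idx[, .tets[tt, ], drop = FALSE]
    neg <- matrix(F[vi] < 0, nrow(vi), 4L)
    code <- neg[, 1] + 2L * neg[, 2] + 4L * neg[, 3] + 8L * neg[, 4]
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (length(sel) == 0L) next
      inside <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) != 0L)
      outside <- setdiff(1:4, inside)
      V <- vi[sel, , drop = FALSE]
      if (length(inside) == 1L || length(outside) == 1L) {
        lone <- if (length(inside) == 1L) inside else outside
        oth <- setdiff(1:4, lone)
        p1 <- interp(V[, lone], V[, oth[1]])
        p2 <- interp(V[, lone], V[, oth[2]])
        p3 <- interp(V[, lone], V[, oth[3]])
        nt <- nt + 1L; tri_pts[[nt]] <- cbind(p1, p2, p3)
      } else {
        a1 <- inside[1]; a2 <- inside[2]; b1 <- outside[1]; b2 <- outside[2]
        q1 <- interp(V[, a1], V[, b1])
        q2 <- interp(V[, a1], V[, b2])
        q3 <- interp(V[, a2], V[, b2])
        q4 <- interp(V[, a2], V[, b1])
        nt <- nt + 1L; tri_pts[[nt]] <- cbind(q1, q2, q3)
        nt <- nt + 1L; tri_pts[[nt]] <- cbind(q1, q3, q4)
      }
      if (nt >= length(tri_pts)) tri_pts <- c(tri_pts, vector("list", 64L))
    }
  }
  tri_pts <- tri_pts[seq_len(nt)]
  if (nt == 0L) stopf("no zero-level surface found in the implicit field")
  tri <- do.call(rbind, tri_pts)            # each row: 3 concatenated points
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  m <- nrow(tri)
  faces <- cbind(seq_len(m), seq_len(m) + m, seq_len(m) + 2L * m)
  # weld coincident vertices
  key <- paste(round(pts[, 1], 7), round(pts[, 2], 7), round(pts[, 3], 7))
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid[faces], ncol = 3L)
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!deg, , drop = FALSE]
  list(vertices = verts, faces = faces)
}

#' Reconstruct a triangulated surface from an oriented point set
#'
#' Non-planar point sets are reconstructed by contouring an implicit
#' signed-distance field (distance to the tangent plane of the nearest
#' sample, requiring normals) with marching tetrahedra on a regular grid.
#' Planar sets (detected by principal-component analysis) are triangulated
#' by 2D Delaunay in the plane, which preserves the input points exactly.
#'
#' @param points numeric n x 3 matrix (mm), n >= 4.
#' @param normals numeric n x 3 matrix of unit normals; required for
#'   non-planar sets.
#' @param tolerance mm; a warning is issued if any input point ends up
#'   farther than this from the reconstructed surface. Default 0.1 mm.
#' @param grid_n grid resolution per axis for the implicit contouring.
#' @return A [surface_mesh].
#' @export
reconstruct_surface <- function(points, normals = NULL, tolerance = 0.1,
                                grid_n = 48L) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stopf("need at least 4 points")
  cen <- colMeans(points)
  X <- sweep(points, 2, cen)
  sv <- svd(X)
  if (sv$d[1] < 1e-12) stopf("all points are identical")
  planar <- sv$d[3] < 1e-7 * sv$d[1]
  if (planar) {
    if (sv$d[2] < 1e-9 * sv$d[1]) stopf("points are collinear")
    uv <- X %*% sv$v[, 1:2]
    tris <- delaunay2d(uv)
    mesh <- surface_mesh(points, tris)
  } else {
    if (is.null(normals)) stopf("normals are required for non-planar reconstruction")
    normals <- as.matrix(normals)
    bb <- apply(points, 2, range)
    spacing <- max(bb[2, ] - bb[1, ]) / (grid_n - 4L)
    axes <- lapply(1:3, function(a)
      seq(bb[1, a] - 2 * spacing, bb[2, a] + 2 * spacing, by = spacing))
    grid <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
    # signed distance to tangent plane of nearest sample, chunked
    F <- numeric(nrow(grid))
    sq <- rowSums(points^2)
    chunk <- 4000L
    for (s in seq(1L, nrow(grid), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(grid))
      g <- grid[idx, , drop = FALSE]
      d2 <- outer(rowSums(g^2), sq, "+") - 2 * g %*% t(points)
      nn <- max.col(-d2, ties.method = "first")
      F[idx] <- rowSums((g - points[nn, , drop = FALSE]) * normals[nn, , drop = FALSE])
    }
    mt <- march_tetrahedra(F, axes[[1]], axes[[2]], axes[[3]])
    mesh <- surface_mesh(mt$vertices, mt$faces)
  }
  dmax <- max(vapply(seq_len(nrow(points)), function(i)
    closest_point_on_mesh(mesh, points[i, ])$distance, numeric(1)))
  if (dmax > tolerance)
    warning(sprintf("reconstruction deviates from input by up to %.4f mm", dmax))
  mesh
}
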