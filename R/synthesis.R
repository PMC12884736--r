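# Tile-to-surface synthesis: projecting fused tiles onto mesh facets via
# the calibrated homography, Markov-random-field view selection, Poisson
# brightness blending across seams, and rendering utilities.

#' Project a fused tile onto mesh facets
#'
#' The tile's camera frame is anchored at `center` (the grid center the
#' optical axis points through) with axes given by the pose's Z-X-Y Euler
#' matrix; surface points are projected orthogonally onto the tangent
#' (sensor) plane, converted to um, and mapped to pixels by the
#' homography. Facets whose centroid falls inside the tile footprint are
#' assigned per-vertex texture coordinates.
#'
#' @param tile a `fused_tile` (or a plain matrix).
#' @param pose a [microscope_pose].
#' @param H_hat a `homography` mapping board-plane um to centered pixels.
#' @param mesh a [surface_mesh].
#' @param center length-3 anchor point, mm; defaults to
#'   `(pose$x, pose$y, 0)` (vertical viewing of a near-planar sample).
#' @param pixel_N sensor side, pixels; tile images smaller than the
#'   sensor are treated as the full FOV downsampled.
#' @return List: `assigned` (logical per facet), `uv` (list per facet of
#'   3 x 2 vertex pixel coordinates in tile units), `view_axis`,
#'   `center`, `tile_dim`.
#' @export
project_tile <- function(tile, pose, H_hat, mesh, center = NULL,
                         pixel_N = NULL) {
  img <- if (inherits(tile, "fused_tile")) tile$image else tile
  Hm <- if (inherits(H_hat, "homography")) H_hat$H else as.matrix(H_hat)
  if (abs(det(Hm)) <= 1e-12) stopf("singular homography")
  if (is.null(pixel_N))
    pixel_N <- if (inherits(H_hat, "homography") && !is.null(H_hat$pixel_N))
      H_hat$pixel_N else 5120L
  if (is.null(center)) center <- c(pose$x, pose$y, 0)
  R <- euler_zxy(pose$rx, pose$ry, pose$rz)
  scale <- ncol(img) / pixel_N

  to_pixel <- function(pts) {
    rel <- sweep(pts, 2, center)
    uv_um <- cbind(rel %*% R[, 1], rel %*% R[, 2]) * 1000
    q <- cbind(uv_um, 1) %*% t(Hm)
    px <- q[, 1:2, drop = FALSE] / q[, 3]
    (px + pixel_N / 2) * scale
  }

  v <- mesh$vertices; f <- mesh$faces
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  cpx <- to_pixel(fc)
  assigned <- cpx[, 1] >= 0 & cpx[, 1] <= ncol(img) &
    cpx[, 2] >= 0 & cpx[, 2] <= nrow(img)
  vpx <- to_pixel(v)
  uv <- vector("list", nrow(f))
  for (i in which(assigned)) uv[[i]] <- vpx[f[i, ], , drop = FALSE]
  list(assigned = assigned, uv = uv, view_axis = R[, 3], center = center,
       tile_dim = dim(img), pixel_N = pixel_N, scale = scale)
}

#' Invert the pixel mapping of a projection
#'
#' Maps tile pixel coordinates back to 3D points on the camera tangent
#' plane; the inverse of the forward map in [project_tile].
#'
#' @param px n x 2 pixel coordinates (tile units).
#' @param proj the list returned by [project_tile].
#' @param pose the [microscope_pose] used for the projection.
#' @param H_hat the homography used for the projection.
#' @return n x 3 matrix of positions, mm.
#' @export
unproject_pixel <- function(px, proj, pose, H_hat) {
  Hm <- if (inherits(H_hat, "homography")) H_hat$H else as.matrix(H_hat)
  R <- euler_zxy(pose$rx, pose$ry, pose$rz)
  pc <- as.matrix(px) / proj$scale - proj$pixel_N / 2
  q <- cbind(pc, 1) %*% t(solve(Hm))
  uv_mm <- (q[, 1:2, drop = FALSE] / q[, 3]) / 1000
  sweep(uv_mm[, 1] %o% R[, 1] + uv_mm[, 2] %o% R[, 2], 2, -proj$center)
}

#' Markov-random-field view selection
#'
#' Assigns one candidate tile to each facet by minimizing
#' `sum unary(facet, tile) + lambda * sum [neighbor labels differ]`,
#' with `unary = 1 - cos(angle between facet normal and tile view axis)`.
#' Solved by iterated conditional modes from the best-unary
#' initialization; the energy never increases across sweeps. Facets with
#' no candidate stay unassigned (NA).
#'
#' @param mesh a [surface_mesh].
#' @param candidates list per facet; each element a list of entries
#'   `list(tile_id =, view_axis =)` (possibly empty).
#' @param lambda smoothness weight; 0 decouples the facets.
#' @param max_sweeps ICM sweep limit.
#' @return List: `labels` (tile id per facet, NA when unassigned),
#'   `energy`, `energy_trace`.
#' @export
select_views <- function(mesh, candidates, lambda = 0.5, max_sweeps = 20L) {
  nf <- nrow(mesh$faces)
  if (length(candidates) != nf) stopf("candidates must align with facets")
  fn <- facet_normals_raw(mesh$vertices, mesh$faces)
  fn <- fn / pmax(row_norms(fn), 1e-300)
  unary <- lapply(seq_len(nf), function(i) {
    cs <- candidates[[i]]
    if (length(cs) == 0L) return(numeric(0))
    vapply(cs, function(cand)
      1 - sum(fn[i, ] * normalize(cand$view_axis)), numeric(1))
  })
  cand_ids <- lapply(candidates, function(cs)
    vapply(cs, function(cand) as.integer(cand$tile_id), integer(1)))
  # facet adjacency via shared edges
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  fidx <- rep(seq_len(nf), 3L)
  sp <- split(fidx, ekey)
  nbrs <- vector("list", nf)
  for (grp in sp) {
    if (length(grp) == 2L) {
      nbrs[[grp[1]]] <- c(nbrs[[grp[1]]], grp[2])
      nbrs[[grp[2]]] <- c(nbrs[[grp[2]]], grp[1])
    }
  }
  # best-unary initialization
  lab <- rep(NA_integer_, nf)   # index into the candidate list per facet
  for (i in seq_len(nf)) if (length(unary[[i]]) > 0L)
    lab[i] <- which.min(unary[[i]])
  energy <- function() {
    e <- sum(vapply(seq_len(nf), function(i)
      if (is.na(lab[i])) 0 else unary[[i]][lab[i]], numeric(1)))
    for (i in seq_len(nf)) for (j in nbrs[[i]]) if (j > i) {
      li <- if (is.na(lab[i])) NA else cand_ids[[i]][lab[i]]
      lj <- if (is.na(lab[j])) NA else cand_ids[[j]][lab[j]]
      if (!is.na(li) && !is.na(lj) && li != lj) e <- e + lambda
    }
    e
  }
  trace <- energy()
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(nf)) {
      k <- length(unary[[i]])
      if (k <= 1L) next
      nb_ids <- vapply(nbrs[[i]], function(j)
        if (is.na(lab[j])) NA_integer_ else cand_ids[[j]][lab[j]], integer(1))
      costs <- vapply(seq_len(k), function(a)
        unary[[i]][a] + lambda * sum(!is.na(nb_ids) & nb_ids != cand_ids[[i]][a]),
        numeric(1))
      best <- which.min(costs)
      if (best != lab[i]) {
        lab[i] <- best
        changed <- TRUE
      }
    }
    trace <- c(trace, energy())
    if (!changed) break
  }
  labels <- rep(NA_integer_, nf)
  ok <- !is.na(lab)
  labels[ok] <- vapply(which(ok), function(i) cand_ids[[i]][lab[i]], integer(1))
  list(labels = labels, energy = tail(trace, 1), energy_trace = trace)
}

# ---- Poisson seam blending --------------------------------------------

lap5 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  i <- 2:(n1 - 1); j <- 2:(n2 - 1)
  out[i, j] <- 4 * m[i, j] - m[i - 1, j] - m[i + 1, j] - m[i, j - 1] - m[i, j + 1]
  out
}

seam_edge <- function(patch, side) {
  switch(side,
         left = patch[, 1],
         right = patch[, ncol(patch)],
         top = patch[1, ],
         bottom = patch[nrow(patch), ],
         stopf("unknown seam side: %s", side))
}

`seam_edge<-` <- function(patch, side, value) {
  switch(side,
         left = patch[, 1] <- value,
         right = patch[, ncol(patch)] <- value,
         top = patch[1, ] <- value,
         bottom = patch[nrow(patch), ] <- value)
  patch
}

#' Mean cross-seam intensity step
#'
#' @param atlas list of patches (numeric matrices).
#' @param seam_set list of seams `list(a =, side_a =, b =, side_b =)`.
#' @return Mean absolute intensity jump across all seams.
#' @export
seam_step <- function(atlas, seam_set) {
  if (length(seam_set) == 0L) return(0)
  mean(vapply(seam_set, function(s)
    mean(abs(seam_edge(atlas[[s$a]], s$side_a) -
               seam_edge(atlas[[s$b]], s$side_b))), numeric(1)))
}

#' Poisson brightness blending across seams
#'
#' Per patch, solves the discrete Poisson equation with the gradient
#' field of the source patch and Dirichlet boundary values: seam edges
#' take the average of the two adjoining patch edges, other boundary
#' pixels keep their source values. Interior gradients are preserved
#' while brightness steps across seams are removed.
#'
#' @param atlas list of patches (numeric matrices, >= 3 x 3).
#' @param seam_set list of seams `list(a =, side_a =, b =, side_b =)`
#'   (patch indices into `atlas` and sides "left"/"right"/"top"/
#'   "bottom"); adjoining edges must have equal length.
#' @param tol residual tolerance of the linear solve.
#' @return The blended atlas (same structure).
#' @export
blend_brightness <- function(atlas, seam_set, tol = 1e-6) {
  if (length(seam_set) == 0L) return(atlas)
  targets <- lapply(atlas, identity)
  for (s in seam_set) {
    ea <- seam_edge(atlas[[s$a]], s$side_a)
    eb <- seam_edge(atlas[[s$b]], s$side_b)
    if (length(ea) != length(eb)) stopf("seam edges differ in length")
    avg <- (ea + eb) / 2
    seam_edge(targets[[s$a]], s$side_a) <- avg
    seam_edge(targets[[s$b]], s$side_b) <- avg
  }
  touched <- unique(unlist(lapply(seam_set, function(s) c(s$a, s$b))))
  for (p in touched) {
    src <- atlas[[p]]
    n1 <- nrow(src); n2 <- ncol(src)
    if (n1 < 3L || n2 < 3L) stopf("patch too small to blend")
    interior <- matrix(FALSE, n1, n2)
    interior[2:(n1 - 1), 2:(n2 - 1)] <- TRUE
    idx <- matrix(0L, n1, n2)
    idx[interior] <- seq_len(sum(interior))
    ii <- which(interior, arr.ind = TRUE)
    nun <- nrow(ii)
    b <- lap5(src)[interior]
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    add <- function(i, j, x) {
      trip_i <<- c(trip_i, i); trip_j <<- c(trip_j, j); trip_x <<- c(trip_x, x)
    }
    add(seq_len(nun), seq_len(nun), rep(4, nun))
    bound <- targets[[p]]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- ii[, 1] + d[1]; nj <- ii[, 2] + d[2]
      nl <- idx[cbind(ni, nj)]
      inn <- nl > 0L
      add(which(inn), nl[inn], rep(-1, sum(inn)))
      b[!inn] <- b[!inn] + bound[cbind(ni[!inn], nj[!inn])]
    }
    Amat <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                 dims = c(nun, nun))
    x <- as.numeric(Matrix::solve(Amat, b))
    res <- sqrt(mean((as.numeric(Amat %*% x) - b)^2))
    if (res > tol) stopf("Poisson solve did not converge (residual %.2e)", res)
    out <- targets[[p]]
    out[interior] <- x
    targets[[p]] <- out
  }
  targets
}

#' Invert image intensities
#'
#' Pixelwise `I_max - I`; applied so cell nuclei appear darker than the
#' cytoplasm, matching conventional histology contrast.
#'
#' @param image numeric matrix or array.
#' @param i_max intensity ceiling; default 255.
#' @return Inverted image.
#' @export
invert_intensity <- function(image, i_max = 255) {
  i_max - image
}

#' Color moment loss between two images
#'
#' `L = MSE(mean_a, mean_b) + MSE(std_a, std_b)` over per-channel means
#' and standard deviations: the color-consistency penalty used when
#' training a virtual-staining renderer. Depends only on the channel
#' moments, so it is invariant to spatial permutations.
#'
#' @param img_a,img_b numeric matrices (one channel) or h x w x c arrays
#'   with equal channel counts.
#' @param reduce `"mean"` (average squared differences over channels,
#'   default) or `"sum"`.
#' @return Non-negative scalar; 0 for identical moments.
#' @export
color_moment_loss <- function(img_a, img_b, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  chans <- function(x) {
    if (is.matrix(x)) list(x)
    else lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  }
  ca <- chans(img_a); cb <- chans(img_b)
  if (length(ca) != length(cb)) stopf("channel counts differ")
  mu_a <- vapply(ca, mean, numeric(1)); mu_b <- vapply(cb, mean, numeric(1))
  sd_a <- vapply(ca, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  sd_b <- vapply(cb, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  agg <- if (reduce == "mean") mean else sum
  agg((mu_a - mu_b)^2) + agg((sd_a - sd_b)^2)
}

# default stain absorption vectors (optical-density RGB)
.hematoxylin_od <- c(0.650, 0.704, 0.286)
.eosin_od <- c(0.072, 0.990, 0.105)

#' Deterministic pseudo-H&E rendering
#'
#' Beer-Lambert mapping of registered nuclear and cytoplasm channels to
#' RGB: `channel_k = 255 * exp(-(cH_k * nuclear + cE_k * background))`
#' with fixed hematoxylin/eosin absorption vectors. Zero signal renders
#' white; increasing signal monotonically darkens every channel.
#'
#' @param nuclear_image,background_image registered single-channel
#'   matrices on `[0, i_max]`.
#' @param c_h,c_e length-3 absorption vectors (optical density per unit
#'   signal).
#' @param i_max input intensity ceiling; default 255.
#' @return h x w x 3 numeric array on `[0, 255]`.
#' @export
pseudo_he_render <- function(nuclear_image, background_image,
                             c_h = .hematoxylin_od, c_e = .eosin_od,
                             i_max = 255) {
  if (!all(dim(nuclear_image) == dim(background_image)))
    stopf("input shapes differ")
  nuc <- nuclear_image / i_max
  bg <- background_image / i_max
  out <- array(0, c(dim(nuc), 3L))
  for (k in 1:3) out[, , k] <- 255 * exp(-(c_h[k] * nuc + c_e[k] * bg))
  out
}
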