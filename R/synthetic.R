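# Synthetic fixture generators emulating every input the instrument
# would produce: tissue surface meshes, fluorescence tissue textures with
# ground-truth nucleus masks, defocus stacks, calibration scenes and
# labeled margin datasets. All generators are pure functions of
# (parameters, seed).

#' Tissue texture parameters
#'
#' Positive-margin textures emulate malignant tissue: higher nuclear
#' density, larger nuclei and brighter nuclear signal than their paired
#' negative class, with relaxed spacing (disorganized arrangement).
#'
#' @param class "positive" or "negative".
#' @param nuclear_density nuclei per mm^2.
#' @param radius_mean,radius_sd nucleus radius distribution, um.
#' @param nuclear_intensity,cytoplasm_intensity 0-255 fluorescence
#'   levels (nuclei brighter, pre-inversion).
#' @param noise_sd additive Gaussian noise, intensity units.
#' @return A `tissue_params` object.
#' @export
tissue_params <- function(class = c("negative", "positive"),
                          nuclear_density = NULL,
                          radius_mean = NULL, radius_sd = 0.5,
                          nuclear_intensity = NULL,
                          cytoplasm_intensity = 60,
                          noise_sd = 10) {
  class <- match.arg(class)
  nuclear_density <- nuclear_density %||%
    if (class == "positive") 3000 else 1500
  radius_mean <- radius_mean %||% if (class == "positive") 4.5 else 3.5
  nuclear_intensity <- nuclear_intensity %||%
    if (class == "positive") 200 else 180
  if (nuclear_density < 0 || radius_mean <= 0)
    stopf("invalid tissue parameters")
  structure(list(class = class, nuclear_density = nuclear_density,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 nuclear_intensity = nuclear_intensity,
                 cytoplasm_intensity = cytoplasm_intensity,
                 noise_sd = noise_sd),
            class = "tissue_params")
}

#' Defocus model
#'
#' Frames away from the focus elevation are blurred with an isotropic
#' Gaussian whose sigma grows linearly with defocus distance.
#'
#' @param focus_elevation mm.
#' @param blur_scale blur sigma in pixels per mm of defocus (>= 0).
#' @return A `defocus_model` object.
#' @export
defocus_model <- function(focus_elevation = 0, blur_scale = 20) {
  if (blur_scale < 0) stopf("blur_scale must be >= 0")
  structure(list(focus_elevation = focus_elevation,
                 blur_scale = blur_scale),
            class = "defocus_model")
}

# triangulate a rectangular grid of (nr x nc) vertices
grid_faces <- function(nr, nc) {
  idx <- function(i, j) (j - 1L) * nr + i
  f <- matrix(0L, 2L * (nr - 1L) * (nc - 1L), 3L)
  k <- 0L
  for (j in seq_len(nc - 1L)) for (i in seq_len(nr - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c_ <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
    f[k + 1L, ] <- c(a, b, d)
    f[k + 2L, ] <- c(a, d, c_)
    k <- k + 2L
  }
  f
}

#' Generate a synthetic tissue surface mesh
#'
#' Shapes at the scale of an excised specimen (default 15 x 15 mm with
#' up to 10 mm height variation): a flat plane, a hemisphere, a
#' half-ellipsoid, or a plane with a seeded smooth random height field
#' ("bumpy": a sum of random-phase sinusoids rescaled to the requested
#' amplitude).
#'
#' @param shape one of "plane", "hemisphere", "ellipsoid", "bumpy".
#' @param extent plane edge length, mm (plane/bumpy).
#' @param radius hemisphere radius or length-3 ellipsoid semi-axes, mm.
#' @param amplitude bumpy height amplitude, mm.
#' @param n vertex resolution (grid side or ring count).
#' @param seed RNG seed (bumpy only).
#' @return A [surface_mesh].
#' @export
make_surface <- function(shape = c("plane", "hemisphere", "ellipsoid", "bumpy"),
                         extent = 15, radius = 7.5, amplitude = 2,
                         n = 40L, seed = NULL) {
  shape <- match.arg(shape)
  if (extent <= 0 || any(radius <= 0) || n < 2L) stopf("invalid extents")
  if (shape %in% c("plane", "bumpy")) {
    xs <- seq(-extent / 2, extent / 2, length.out = n)
    g <- expand.grid(x = xs, y = xs)
    z <- rep(0, nrow(g))
    if (shape == "bumpy") {
      z <- with_seed(seed, {
        zz <- rep(0, nrow(g))
        for (kk in 1:6) {
          fr <- runif(2, 0.05, 0.2)
          ph <- runif(1, 0, 2 * pi)
          zz <- zz + runif(1, 0.5, 1) *
            sin(2 * pi * (fr[1] * g$x + fr[2] * g$y) + ph)
        }
        zz
      })
      z <- z / max(abs(z)) * amplitude
    }
    mesh <- surface_mesh(cbind(g$x, g$y, z), grid_faces(n, n))
    if (shape == "plane") {
      # exact vertical normals (tessellation-independent)
      mesh$normals <- matrix(rep(c(0, 0, 1), each = nrow(mesh$vertices)),
                             ncol = 3)
    }
    mesh
  } else {
    ax <- if (length(radius) == 3L) radius else rep(radius, 3L)
    nring <- n
    nseg <- 2L * n
    verts <- matrix(c(0, 0, ax[3]), 1, 3)          # apex
    norms <- matrix(c(0, 0, 1), 1, 3)
    ring_start <- integer(nring)
    for (r in seq_len(nring)) {
      th <- r / nring * pi / 2
      ring_start[r] <- nrow(verts) + 1L
      ang <- (seq_len(nseg) - 1L) / nseg * 2 * pi
      p <- cbind(ax[1] * sin(th) * cos(ang),
                 ax[2] * sin(th) * sin(ang),
                 ax[3] * cos(th))
      # outward ellipsoid normal: gradient of the implicit surface
      nr_ <- cbind(p[, 1] / ax[1]^2, p[, 2] / ax[2]^2, p[, 3] / ax[3]^2)
      nr_ <- nr_ / row_norms(nr_)
      verts <- rbind(verts, p)
      norms <- rbind(norms, nr_)
    }
    faces <- matrix(0L, 0L, 3L)
    # apex fan
    first <- ring_start[1]
    for (s in seq_len(nseg)) {
      s2 <- s %% nseg + 1L
      faces <- rbind(faces, c(1L, first + s - 1L, first + s2 - 1L))
    }
    for (r in seq_len(nring - 1L)) {
      a0 <- ring_start[r]; b0 <- ring_start[r + 1L]
      for (s in seq_len(nseg)) {
        s2 <- s %% nseg + 1L
        faces <- rbind(faces,
                       c(a0 + s - 1L, b0 + s - 1L, b0 + s2 - 1L),
                       c(a0 + s - 1L, b0 + s2 - 1L, a0 + s2 - 1L))
      }
    }
    surface_mesh(verts, faces, norms)
  }
}

#' Generate a fluorescence tissue texture with ground truth
#'
#' Nuclei are placed by dart-throwing Poisson-disk sampling at the
#' stated density (minimum spacing `radius_mean` for negative tissue,
#' relaxed to `0.3 * radius_mean` for the disorganized positive class),
#' with truncated-normal radii, drawn as bright disks on dimmer
#' cytoplasm plus Gaussian noise. The exact nucleus mask is returned.
#'
#' @param params a [tissue_params].
#' @param extent_mm image edge length, mm.
#' @param pixel_pitch_um sample-plane pixel pitch, um (0.9 at 5x).
#' @param seed RNG seed.
#' @return List: `image` (matrix, 0-255), `mask` (logical ground
#'   truth), `centers_um`, `radii_um`.
#' @export
make_tissue_texture <- function(params, extent_mm = 0.4608,
                                pixel_pitch_um = 0.9, seed = 1L) {
  stopifnot(inherits(params, "tissue_params"))
  if (extent_mm <= 0 || pixel_pitch_um <= 0) stopf("invalid extent or pitch")
  npx <- round(extent_mm * 1000 / pixel_pitch_um)
  with_seed(seed, {
    area_mm2 <- extent_mm^2
    n_target <- rpois(1, params$nuclear_density * area_mm2)
    spacing <- if (params$class == "positive")
      0.3 * params$radius_mean else params$radius_mean
    ext_um <- extent_mm * 1000
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_target && tries < 40L * max(n_target, 1L)) {
      tries <- tries + 1L
      cand <- runif(2, 0, ext_um)
      if (nrow(centers) == 0L ||
          min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
            spacing^2)
        centers <- rbind(centers, cand)
    }
    if (n_target > 0L && nrow(centers) < 0.5 * n_target)
      stopf("nucleus placement failed: density too high for the spacing rule")
    radii <- pmax(abs(rnorm(nrow(centers), params$radius_mean,
                            params$radius_sd)), 0.5)
    xs <- (seq_len(npx) - 0.5) * pixel_pitch_um
    mask <- matrix(FALSE, npx, npx)
    for (i in seq_len(nrow(centers))) {
      rx <- which(abs(xs - centers[i, 1]) <= radii[i])
      ry <- which(abs(xs - centers[i, 2]) <= radii[i])
      if (length(rx) == 0L || length(ry) == 0L) next
      dd <- outer((xs[ry] - centers[i, 2])^2, (xs[rx] - centers[i, 1])^2, "+")
      mask[ry, rx] <- mask[ry, rx] | dd <= radii[i]^2
    }
    img <- matrix(params$cytoplasm_intensity, npx, npx)
    img[mask] <- params$nuclear_intensity
    img <- img + matrix(rnorm(npx^2, 0, params$noise_sd), npx)
    list(image = clamp(img, 0, 255), mask = mask,
         centers_um = centers, radii_um = radii)
  })
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Simulate a focal stack from a sharp image
#'
#' Frame i is the sharp image convolved with a Gaussian of sigma
#' `blur_scale * |elevation_i - focus_elevation|` (sigma 0 leaves the
#' frame untouched).
#'
#' @param sharp_image numeric matrix.
#' @param elevations strictly increasing frame elevations, mm.
#' @param defocus a [defocus_model].
#' @param grid_id stack identifier.
#' @return A [focal_stack].
#' @export
make_focal_stack <- function(sharp_image, elevations,
                             defocus = defocus_model(), grid_id = 1L) {
  stopifnot(inherits(defocus, "defocus_model"))
  frames <- lapply(elevations, function(e) {
    sigma <- defocus$blur_scale * abs(e - defocus$focus_elevation)
    if (sigma < 1e-9) sharp_image
    else conv_sep(sharp_image, gaussian_kernel(sigma))
  })
  focal_stack(frames, elevations, grid_id)
}

#' Simulate a chessboard calibration scene
#'
#' Projects the 13 chessboard dots through `H = A . B` built from the
#' true magnification and extrinsic pose, then adds seeded Gaussian
#' pixel noise.
#'
#' @param true_m true magnification.
#' @param true_pose an `extrinsic_pose`; identity by default.
#' @param noise_px Gaussian pixel noise sd.
#' @param seed RNG seed.
#' @param du,pixel_N sensor parameters.
#' @return List: `pixels` (13 x 2 centered pixels), `board_mm`
#'   (13 x 2), `A`, `B`, `H` (true homography), `pixel_N`.
#' @export
make_calibration_scene <- function(true_m = 5, true_pose = extrinsic_pose(),
                                   noise_px = 0, seed = 1L,
                                   du = 4.5, pixel_N = 5120L) {
  if (true_m <= 0) stopf("true_m must be > 0")
  A <- intrinsic_matrix(true_m, du, pixel_N)
  H <- compose_homography(A, true_pose)
  board <- chessboard_model()$dots
  px <- project_board(H, board)
  if (noise_px > 0)
    px <- px + with_seed(seed, matrix(rnorm(length(px), 0, noise_px),
                                      nrow(px)))
  list(pixels = px, board_mm = board, A = A, B = true_pose, H = H,
       pixel_N = as.integer(pixel_N))
}

#' Simulate the tile a camera would capture of a surface pattern
#'
#' For each tile pixel, the pixel is mapped through the inverse
#' homography onto the camera tangent plane anchored at `center`, and
#' the pattern function is evaluated at the resulting (x, y) surface
#' coordinates. The paraxial stand-in for image formation used by the
#' end-to-end synthetic pipeline.
#'
#' @param pattern_fn function(x_mm, y_mm) -> intensity, vectorized.
#' @param pose a [microscope_pose].
#' @param H_hat homography (board um -> centered pixels).
#' @param center length-3 anchor point on the surface, mm.
#' @param tile_px tile image side, pixels.
#' @param pixel_N full sensor side, pixels.
#' @return `tile_px` x `tile_px` numeric matrix.
#' @export
render_tile <- function(pattern_fn, pose, H_hat, center, tile_px = 128L,
                        pixel_N = 5120L) {
  Hm <- if (inherits(H_hat, "homography")) H_hat$H else as.matrix(H_hat)
  R <- euler_zxy(pose$rx, pose$ry, pose$rz)
  scale <- tile_px / pixel_N
  gp <- expand.grid(col = seq_len(tile_px) - 0.5, row = seq_len(tile_px) - 0.5)
  pc <- cbind(gp$col, gp$row) / scale - pixel_N / 2
  q <- cbind(pc, 1) %*% t(solve(Hm))
  uv_mm <- (q[, 1:2, drop = FALSE] / q[, 3]) / 1000
  pts <- matrix(center, nrow(uv_mm), 3, byrow = TRUE) +
    uv_mm[, 1] %o% R[, 1] + uv_mm[, 2] %o% R[, 2]
  matrix(pattern_fn(pts[, 1], pts[, 2]), tile_px, tile_px, byrow = TRUE)
}

#' Generate a labeled margin dataset
#'
#' Generates positive- and negative-class tissue textures, tiles them
#' into 128 x 128 subimages, and attaches labels. Reproducible per
#' seed.
#'
#' @param n_pos,n_neg subimage counts per class (>= 1).
#' @param pos_params,neg_params [tissue_params] per class.
#' @param seed RNG seed.
#' @param size subimage edge, pixels.
#' @param pixel_pitch_um sample-plane pixel pitch.
#' @return List of `sub_image` with labels set.
#' @export
make_margin_dataset <- function(n_pos, n_neg,
                                pos_params = tissue_params("positive"),
                                neg_params = tissue_params("negative"),
                                seed = 1L, size = 128L,
                                pixel_pitch_um = 0.9) {
  if (n_pos < 1L || n_neg < 1L) stopf("need >= 1 subimage per class")
  per_tex <- 4L   # 2 x 2 tiles per generated texture
  gen_class <- function(n, params, label, seed0) {
    ext <- 2 * size * pixel_pitch_um / 1000
    out <- list()
    t_i <- 0L
    while (length(out) < n) {
      t_i <- t_i + 1L
      tex <- make_tissue_texture(params, extent_mm = ext,
                                 pixel_pitch_um = pixel_pitch_um,
                                 seed = seed0 + t_i)
      tiles <- tile_image(tex$image, size = size,
                          pixel_mm = pixel_pitch_um / 1000,
                          label = label)
      out <- c(out, tiles[seq_len(min(per_tex, length(tiles)))])
    }
    out[seq_len(n)]
  }
  c(gen_class(n_pos, pos_params, "positive", seed * 1000L),
    gen_class(n_neg, neg_params, "negative", seed * 1000L + 500L))
}
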