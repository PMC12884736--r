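# Focal-stack fusion (extended depth of field), illumination
# normalization, and FOV arithmetic. Images are numeric matrices on a
# 0-255 intensity scale.

#' Field-of-view edge length
#'
#' `l = du * pixel_N / m`, converted to mm: the sample-plane edge imaged
#' in one snapshot. With the standard sensor (du = 4.5 um, 5120 px) the
#' 5x/10x/20x objectives give 4.608, 2.304 and 1.152 mm.
#'
#' @param objective an [objective_spec] (supplies `m`).
#' @param intrinsics a `camera_intrinsics` (supplies `du`, `pixel_N`);
#'   defaults to the standard sensor at the objective's magnification.
#' @return FOV edge length in mm.
#' @export
compute_fov <- function(objective, intrinsics = NULL) {
  m <- if (inherits(objective, "objective_spec")) objective$magnification
       else as.numeric(objective)
  if (!is_scalar_num(m) || m <= 0) stopf("magnification must be > 0")
  if (is.null(intrinsics)) intrinsics <- intrinsic_matrix(m)
  intrinsics$du * intrinsics$pixel_N / m / 1000
}

#' Focal stack
#'
#' A cluster of same-shape frames of one grid acquired at strictly
#' increasing focus elevations.
#'
#' @param frames list of numeric matrices (equal dimensions).
#' @param elevations numeric vector, mm, aligned with `frames`, strictly
#'   increasing.
#' @param grid_id integer grid identifier.
#' @return A `focal_stack` object.
#' @export
focal_stack <- function(frames, elevations, grid_id = 1L) {
  if (length(frames) < 1L) stopf("need >= 1 frame")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all frames must have the same shape")
  if (length(elevations) != length(frames))
    stopf("elevations must align with frames")
  if (length(elevations) > 1L && any(diff(elevations) <= 0))
    stopf("elevations must be strictly increasing")
  structure(list(frames = frames, elevations = as.numeric(elevations),
                 grid_id = as.integer(grid_id)),
            class = "focal_stack")
}

# ---- separable convolution with reflected borders ---------------------

reflect_index <- function(n, r) {
  idx <- (1 - r):(n + r)
  idx[idx < 1] <- 2 - idx[idx < 1]
  idx[idx > n] <- 2 * n - idx[idx > n]
  idx
}

conv_sep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  n1 <- nrow(img); n2 <- ncol(img)
  P <- img[reflect_index(n1, r), , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (j in seq_along(k))
    out <- out + k[j] * P[j:(j + n1 - 1L), , drop = FALSE]
  P <- out[, reflect_index(n2, r), drop = FALSE]
  out <- matrix(0, n1, n2)
  for (j in seq_along(k))
    out <- out + k[j] * P[, j:(j + n2 - 1L), drop = FALSE]
  out
}

# 5-tap binomial kernel used throughout the pyramid
.binom5 <- c(1, 4, 6, 4, 1) / 16

pyr_down <- function(img) {
  g <- conv_sep(img, .binom5)
  g[seq(1L, nrow(g), by = 2L), seq(1L, ncol(g), by = 2L), drop = FALSE]
}

pyr_up <- function(img, target_dim) {
  z <- matrix(0, target_dim[1], target_dim[2])
  z[seq(1L, target_dim[1], by = 2L), seq(1L, target_dim[2], by = 2L)] <- img
  conv_sep(z, 2 * .binom5)
}

laplacian_pyramid <- function(img, levels) {
  out <- vector("list", levels)
  g <- img
  if (levels > 1L) {
    for (lev in seq_len(levels - 1L)) {
      d <- pyr_down(g)
      out[[lev]] <- g - pyr_up(d, dim(g))
      g <- d
    }
  }
  out[[levels]] <- g
  out
}

reconstruct_pyramid <- function(pyr) {
  g <- pyr[[length(pyr)]]
  if (length(pyr) > 1L) {
    for (lev in (length(pyr) - 1L):1L)
      g <- pyr[[lev]] + pyr_up(g, dim(pyr[[lev]]))
  }
  g
}

#' Fuse a focal stack into one extended-depth-of-field tile
#'
#' Laplacian-pyramid fusion: each frame is decomposed into a pyramid
#' (5-tap binomial kernel, reflected borders); at every band-pass level
#' each coefficient is taken from the frame with the largest absolute
#' response (ties broken toward the lower frame index), and the low-pass
#' top level is averaged across frames. Reconstructing the merged pyramid
#' yields the all-in-focus image. The provenance map records the level-0
#' source frame per pixel.
#'
#' @param stack a [focal_stack].
#' @param levels pyramid depth; default 5, reduced automatically for
#'   small frames.
#' @return A `fused_tile`: `image`, `grid_id`, `provenance`.
#' @export
fuse_stack <- function(stack, levels = 5L) {
  stopifnot(inherits(stack, "focal_stack"))
  nf <- length(stack$frames)
  d <- dim(stack$frames[[1]])
  levels <- max(1L, min(levels, floor(log2(min(d))) - 1L))
  if (nf == 1L) {
    return(structure(list(image = stack$frames[[1]],
                          grid_id = stack$grid_id,
                          provenance = matrix(1L, d[1], d[2])),
                     class = "fused_tile"))
  }
  pyrs <- lapply(stack$frames, laplacian_pyramid, levels = levels)
  fused <- vector("list", levels)
  provenance <- NULL
  if (levels > 1L) {
    for (lev in seq_len(levels - 1L)) {
      coefs <- vapply(pyrs, function(p) as.vector(p[[lev]]),
                      numeric(length(pyrs[[1]][[lev]])))
      sel <- max.col(abs(coefs), ties.method = "first")
      merged <- coefs[cbind(seq_along(sel), sel)]
      fused[[lev]] <- matrix(merged, nrow(pyrs[[1]][[lev]]))
      if (lev == 1L) provenance <- matrix(sel, d[1], d[2])
    }
  }
  top <- Reduce(`+`, lapply(pyrs, function(p) p[[levels]])) / nf
  fused[[levels]] <- top
  if (is.null(provenance)) provenance <- matrix(1L, d[1], d[2])
  # coefficient mixing can ring past the frame envelope; clip to it
  rng <- range(unlist(lapply(stack$frames, range)))
  structure(list(image = clamp(reconstruct_pyramid(fused), rng[1], rng[2]),
                 grid_id = stack$grid_id,
                 provenance = provenance),
            class = "fused_tile")
}

#' Tenengrad sharpness score
#'
#' Mean squared Sobel gradient magnitude; the focus metric used to
#' compare fused tiles with their sharp references.
#'
#' @param img numeric matrix.
#' @return Scalar sharpness score.
#' @export
tenengrad <- function(img) {
  sx <- c(1, 2, 1) / 4
  dx <- c(1, 0, -1)
  # Sobel = smoothing along one axis, differencing along the other
  r <- reflect_index(nrow(img), 1L)
  cidx <- reflect_index(ncol(img), 1L)
  smooth_rows <- function(m, k) {
    P <- m[r, , drop = FALSE]
    k[1] * P[1:nrow(m), ] + k[2] * P[2:(nrow(m) + 1), ] + k[3] * P[3:(nrow(m) + 2), ]
  }
  smooth_cols <- function(m, k) {
    P <- m[, cidx, drop = FALSE]
    k[1] * P[, 1:ncol(m)] + k[2] * P[, 2:(ncol(m) + 1)] + k[3] * P[, 3:(ncol(m) + 2)]
  }
  gx <- smooth_cols(smooth_rows(img, dx), sx)
  gy <- smooth_cols(smooth_rows(img, sx), dx)
  mean(gx^2 + gy^2)
}

#' Histogram equalization of a tile
#'
#' Standard cumulative-histogram equalization to the full 0-255 range,
#' applied per tile after fusion to mitigate illumination variations from
#' surface fluctuations. Constant tiles are returned unchanged.
#'
#' @param image numeric matrix, intensities in `[0, 255]`.
#' @param bins histogram bin count; default 256.
#' @return Equalized matrix on the same scale.
#' @export
equalize_tile <- function(image, bins = 256L) {
  if (length(image) == 0L) stopf("empty image")
  rng <- range(image)
  if (diff(rng) < 1e-12) return(image)
  bin <- pmin(floor(image / 256 * bins), bins - 1L) + 1L
  counts <- tabulate(bin, nbins = bins)
  cdf <- cumsum(counts) / length(image)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (1 - cdf_min < 1e-12) return(image)
  out <- (cdf[bin] - cdf_min) / (1 - cdf_min) * 255
  matrix(out, nrow(image))
}

#' Write / read a focal stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit grayscale pages; elevations and the grid
#' id go to `<path>.json`.
#'
#' @param stack a [focal_stack].
#' @param path TIFF path.
#' @return `path` invisibly, or the [focal_stack].
#' @export
write_focal_stack <- function(stack, path) {
  pages <- lapply(stack$frames, function(f) clamp(f / 255, 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(grid_id = stack$grid_id,
                            elevations_mm = stack$elevations),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_focal_stack
#' @export
read_focal_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  focal_stack(lapply(pages, function(p) p * 255),
              meta$elevations_mm, meta$grid_id)
}
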