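# The homography projection model and the calibration fits.
#
# The microscope is modeled as an infinity-corrected system: an intrinsic
# matrix A = diag(m/du, m/du, 1) (pixels per um), an extrinsic matrix B
# carrying the top two rows of a rotation plus translation (um), and the
# homography H = A.B mapping chessboard-plane coordinates (um) to pixel
# coordinates measured from the image center. Pixel coordinates handed to
# the fitting functions are centered (absolute pixel minus pixel_N/2).

#' Intrinsic camera matrix
#'
#' @param m effective magnification (> 0).
#' @param du sensor pixel pitch, um (> 0); default 4.5.
#' @param pixel_N pixels along one side of the square sensor; default 5120.
#' @return A `camera_intrinsics` object with matrix `A` =
#'   `diag(m/du, m/du, 1)` in pixels per um.
#' @export
intrinsic_matrix <- function(m, du = 4.5, pixel_N = 5120L) {
  if (!is_scalar_num(m) || m <= 0) stopf("magnification m must be > 0")
  if (!is_scalar_num(du) || du <= 0) stopf("pixel pitch du must be > 0")
  A <- diag(c(m / du, m / du, 1))
  structure(list(m = m, du = du, pixel_N = as.integer(pixel_N), A = A),
            class = "camera_intrinsics")
}

#' Extrinsic pose matrix
#'
#' Top two rows of a rotation (`r11..r23`) plus in-plane translation
#' (`tx`, `ty`, um), assembled as the 3x3 matrix acting on chessboard-
#' plane homogeneous coordinates: `[[r11, r12, tx], [r21, r22, ty],
#' [0, 0, 1]]` (the board plane is z = 0, so the third rotation column
#' drops out).
#'
#' @param r11,r12,r13,r21,r22,r23 rotation-row entries.
#' @param tx,ty translation, um.
#' @return An `extrinsic_pose` object with matrix `B`.
#' @export
extrinsic_pose <- function(r11 = 1, r12 = 0, r13 = 0,
                           r21 = 0, r22 = 1, r23 = 0,
                           tx = 0, ty = 0) {
  rows <- rbind(c(r11, r12, r13), c(r21, r22, r23))
  nr <- row_norms(rows)
  if (any(nr > 1 + 1e-9))
    stopf("rotation rows must have norm <= 1")
  B <- rbind(c(r11, r12, tx), c(r21, r22, ty), c(0, 0, 1))
  structure(list(r11 = r11, r12 = r12, r13 = r13,
                 r21 = r21, r22 = r22, r23 = r23,
                 tx = tx, ty = ty, B = B),
            class = "extrinsic_pose")
}

# extrinsic pose from a full 3D rotation matrix (top two rows) and
# translation in um
extrinsic_from_rotation <- function(R, tx = 0, ty = 0) {
  extrinsic_pose(R[1, 1], R[1, 2], R[1, 3], R[2, 1], R[2, 2], R[2, 3],
                 tx, ty)
}

#' Compose the homography H = A . B
#'
#' @param A a `camera_intrinsics`.
#' @param B an `extrinsic_pose`.
#' @param estimated provenance flag: `TRUE` marks an estimated homography
#'   (from commanded stage angles) as opposed to a fitted one.
#' @return A `homography` object.
#' @export
compose_homography <- function(A, B, estimated = FALSE) {
  stopifnot(inherits(A, "camera_intrinsics"), inherits(B, "extrinsic_pose"))
  H <- A$A %*% B$B
  if (abs(det(H)) <= 1e-12) stopf("composed homography is singular")
  structure(list(H = H, estimated = estimated, pixel_N = A$pixel_N),
            class = "homography")
}

as_homography <- function(H, estimated = FALSE, pixel_N = NULL) {
  H <- as.matrix(H)
  if (abs(det(H)) <= 1e-12) stopf("homography is singular")
  structure(list(H = H, estimated = estimated, pixel_N = pixel_N),
            class = "homography")
}

# project board points (mm) through a homography to centered pixels
project_board <- function(H, board_mm) {
  Hm <- if (inherits(H, "homography")) H$H else H
  P <- cbind(as.matrix(board_mm) * 1000, 1)   # mm -> um, homogeneous
  q <- P %*% t(Hm)
  q[, 1:2, drop = FALSE] / q[, 3]
}

#' Calibration chessboard model
#'
#' The physical chessboard: 4 mm squares, a 0.1 mm center dot at the
#' origin O, and 12 auxiliary dots placed symmetrically about O on the
#' square lattice (the four edge-adjacent and four corner-adjacent
#' intersections at 4 mm, plus the four axis intersections at 8 mm).
#'
#' @return A `chessboard_model` with `dots` (13 x 2 matrix, mm; center
#'   first), `square_mm`, `dot_diameter_mm`.
#' @export
chessboard_model <- function() {
  s <- 4
  dots <- rbind(c(0, 0),
                c(s, 0), c(-s, 0), c(0, s), c(0, -s),
                c(s, s), c(-s, s), c(s, -s), c(-s, -s),
                c(2 * s, 0), c(-2 * s, 0), c(0, 2 * s), c(0, -2 * s))
  structure(list(square_mm = s, dot_diameter_mm = 0.1, dots = dots),
            class = "chessboard_model")
}

#' Estimate the effective magnification from dot correspondences
#'
#' Joint least-squares fit of (magnification, in-plane rotation,
#' translation) minimizing pixel reprojection error — the closed-form
#' similarity solution, which is the maximum-likelihood optimum of this
#' parameterization under isotropic pixel noise.
#'
#' @param image_dots n x 2 matrix of centered pixel coordinates.
#' @param board_dots n x 2 matrix of board coordinates, mm.
#' @param du sensor pixel pitch, um.
#' @return List: `m` (estimated magnification), `theta_deg` (in-plane
#'   rotation), `t_px` (translation, pixels), `residual_rms_px`.
#' @export
estimate_magnification <- function(image_dots, board_dots, du = 4.5) {
  Q <- as.matrix(image_dots)
  P <- as.matrix(board_dots) * 1000          # mm -> um
  n <- nrow(Q)
  if (n < 3L || nrow(P) != n) stopf("need >= 3 correspondences")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  if (svd(Pc)$d[2] < 1e-9 * max(svd(Pc)$d[1], 1e-300))
    stopf("board points are collinear")
  C <- crossprod(Qc, Pc) / n
  sv <- svd(C)
  S <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% S %*% t(sv$v)
  sigma_p <- mean(rowSums(Pc^2))
  s <- sum(diag(diag(sv$d) %*% S)) / sigma_p   # pixels per um
  t_px <- colMeans(Q) - s * as.vector(R %*% colMeans(P))
  resid <- Q - (t(s * R %*% t(P)) + matrix(t_px, n, 2, byrow = TRUE))
  list(m = s * du,
       theta_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       t_px = t_px,
       residual_rms_px = sqrt(mean(resid^2)))
}

#' Estimate the extrinsic matrix given intrinsics
#'
#' Linear least squares for the affine extrinsic parameters
#' `(r11, r12, tx; r21, r22, ty)` from board-to-pixel correspondences;
#' `r13`/`r23` are completed so the rows extend to a valid rotation. The
#' parallelism metric reports how far the fitted rows deviate from an
#' in-plane rotation (singular values of the 2x2 block away from 1), and
#' `tilt_deg` the implied out-of-plane tilt.
#'
#' @param A a `camera_intrinsics`.
#' @param image_dots n x 2 centered pixel coordinates (n >= 4).
#' @param board_dots n x 2 board coordinates, mm.
#' @return List: `B` (an `extrinsic_pose`), `residual_rms_px`,
#'   `tilt_deg`, `parallelism`.
#' @export
estimate_extrinsic <- function(A, image_dots, board_dots) {
  stopifnot(inherits(A, "camera_intrinsics"))
  Q <- as.matrix(image_dots)
  P <- as.matrix(board_dots) * 1000
  n <- nrow(Q)
  if (n < 4L || nrow(P) != n) stopf("need >= 4 correspondences")
  X <- cbind(P, 1)
  if (qr(X)$rank < 3L) stopf("degenerate correspondences")
  f <- A$m / A$du
  cf <- qr.solve(X, Q / f)                    # 3 x 2: columns (row1, row2)
  M <- t(cf[1:2, ])                           # 2x2 rotation block
  sv <- svd(M)
  tilt <- acos(clamp(sv$d[2] / max(sv$d[1], 1e-300), -1, 1)) * 180 / pi
  r13 <- sqrt(max(0, 1 - sum(M[1, ]^2)))
  r23 <- if (r13 > 1e-9) -sum(M[1, ] * M[2, ]) / r13 else 0
  B <- extrinsic_pose(M[1, 1], M[1, 2], r13, M[2, 1], M[2, 2], r23,
                      tx = cf[3, 1], ty = cf[3, 2])
  resid <- Q - f * (X %*% cf)
  list(B = B,
       residual_rms_px = sqrt(mean(resid^2)),
       tilt_deg = tilt,
       parallelism = max(abs(sv$d - 1)))
}

#' Positional correction from the centroid deviation after rotation
#'
#' Solves `(offset_x, offset_y, 1)^T = H^-1 (O_x - pixel_N/2,
#' O_y - pixel_N/2, 1)^T` (third component renormalized to 1): the
#' stage-plane correction, in um, that re-centers the chessboard center
#' dot O in the image after a commanded rotation step.
#'
#' @param O_pixel length-2 absolute pixel coordinates of the imaged
#'   center dot.
#' @param H_hat a `homography` (typically estimated from the commanded
#'   step angle).
#' @param pixel_N sensor side length in pixels.
#' @return Named numeric: `offset_x`, `offset_y` (um).
#' @export
rotation_offset <- function(O_pixel, H_hat, pixel_N = 5120L) {
  Hm <- if (inherits(H_hat, "homography")) H_hat$H else as.matrix(H_hat)
  if (abs(det(Hm)) <= 1e-12) stopf("singular homography")
  rhs <- c(O_pixel[1] - pixel_N / 2, O_pixel[2] - pixel_N / 2, 1)
  v <- solve(Hm, rhs)
  if (abs(v[3]) < 1e-15) stopf("offset at infinity (degenerate homography)")
  v <- v / v[3]
  c(offset_x = v[1], offset_y = v[2])
}

#' Interpolate rotation-stage offsets between calibrated steps
#'
#' Piecewise-linear, componentwise interpolation of the positional
#' corrections recorded at calibration step angles. Queries outside the
#' calibrated range are refused (no extrapolation).
#'
#' @param step_angles strictly increasing angles, degrees.
#' @param offsets n x 2 matrix of (offset_x, offset_y) um at each step.
#' @param query angle to interpolate at, degrees.
#' @return Named numeric: `offset_x`, `offset_y` (um).
#' @export
interpolate_offsets <- function(step_angles, offsets, query) {
  offsets <- as.matrix(offsets)
  if (any(diff(step_angles) <= 0)) stopf("step_angles must be strictly increasing")
  if (length(step_angles) != nrow(offsets))
    stopf("step_angles and offsets differ in length")
  if (query < min(step_angles) - 1e-12 || query > max(step_angles) + 1e-12)
    stopf("query %.3f deg outside calibrated range [%.3f, %.3f]",
          query, min(step_angles), max(step_angles))
  c(offset_x = approx(step_angles, offsets[, 1], xout = query)$y,
    offset_y = approx(step_angles, offsets[, 2], xout = query)$y)
}

#' Algebraic least-squares circle fit
#'
#' Kasa fit: linear least squares on `x^2 + y^2 = 2ax + 2by + c`, used to
#' locate the actual rotation axis of the R_z stage from the imaged
#' positions of the chessboard center during incremental rotation.
#'
#' @param points n x 2 matrix (um), n >= 3, not collinear.
#' @return List: `center` (length 2, um), `radius` (um),
#'   `residual_rms` (um).
#' @export
fit_circle <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 3L) stopf("need >= 3 points")
  X <- cbind(2 * P[, 1], 2 * P[, 2], 1)
  if (qr(X, tol = 1e-12)$rank < 3L) stopf("points are collinear")
  y <- rowSums(P^2)
  ab <- qr.solve(X, y)
  center <- ab[1:2]
  radius <- sqrt(ab[3] + sum(center^2))
  r_i <- sqrt(rowSums(sweep(P, 2, center)^2))
  list(center = unname(center), radius = unname(radius),
       residual_rms = sqrt(mean((r_i - radius)^2)))
}

#' Signed skew angle between a fitted line and a stage axis
#'
#' Total-least-squares (principal component) line through the recorded
#' square-vertex positions; returns the signed angle, in degrees, between
#' that line and the named coordinate axis (positive counterclockwise).
#'
#' @param points n x 2 matrix (mm), n >= 2.
#' @param axis `"x"` or `"y"`.
#' @return Signed angle in degrees, in (-90, 90].
#' @export
fit_axis_skew <- function(points, axis = c("x", "y")) {
  axis <- match.arg(axis)
  P <- as.matrix(points)
  if (nrow(P) < 2L) stopf("need >= 2 points")
  Pc <- sweep(P, 2, colMeans(P))
  if (max(abs(Pc)) < 1e-12) stopf("points are identical")
  d <- svd(Pc)$v[, 1]
  if (axis == "x") {
    if (d[1] < 0) d <- -d
    if (abs(d[1]) < 1e-15) return(90)
    atan2(d[2], d[1]) * 180 / pi
  } else {
    if (d[2] < 0) d <- -d
    if (abs(d[2]) < 1e-15) return(90)
    atan2(-d[1], d[2]) * 180 / pi
  }
}

#' Write / read correspondence CSV
#'
#' Columns: `pixel_x`, `pixel_y` (centered pixels), `board_x_mm`,
#' `board_y_mm`.
#'
#' @param correspondences list with `pixels` (n x 2) and `board_mm`
#'   (n x 2).
#' @param path CSV path.
#' @return `path` invisibly, or the correspondences list.
#' @export
write_correspondences <- function(correspondences, path) {
  df <- data.frame(pixel_x = correspondences$pixels[, 1],
                   pixel_y = correspondences$pixels[, 2],
                   board_x_mm = correspondences$board_mm[, 1],
                   board_y_mm = correspondences$board_mm[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  df <- read.csv(path)
  list(pixels = as.matrix(df[, c("pixel_x", "pixel_y")]),
       board_mm = as.matrix(df[, c("board_x_mm", "board_y_mm")]))
}
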