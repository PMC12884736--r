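# Scan-trajectory planning: decompose a surface mesh into FOV-sized grids,
# derive a microscope pose and elevation schedule per grid, and order the
# scan path to minimize rotation-stage motion.

#' Objective lens specification
#'
#' @param magnification dimensionless magnification (> 0).
#' @param dof depth of field, mm (> 0); sets the elevation step between
#'   frames of a focal stack.
#' @param working_distance mm; distance from the objective to the focal
#'   plane, used to place the microscope along the surface normal.
#' @param name optional label (e.g. "5x").
#' @return An `objective_spec` object.
#' @export
objective_spec <- function(magnification, dof, working_distance = 34,
                           name = NULL) {
  if (!is_scalar_num(magnification) || magnification <= 0)
    stopf("magnification must be > 0")
  if (!is_scalar_num(dof) || dof <= 0) stopf("dof must be > 0")
  structure(list(magnification = magnification, dof = dof,
                 working_distance = working_distance,
                 name = name %||% sprintf("%gx", magnification)),
            class = "objective_spec")
}

#' Standard objective presets
#'
#' Presets matching the instrument's interchangeable objectives. The
#' effective axial step (`dof`) is chosen so that typical grid elevation
#' ranges produce focal stacks in the 10-30 frame range.
#'
#' @param name one of "5x", "10x", "20x".
#' @return An [objective_spec].
#' @export
objective_preset <- function(name = c("5x", "10x", "20x")) {
  name <- match.arg(name)
  switch(name,
         "5x" = objective_spec(5, dof = 0.05, working_distance = 34, name = "5x"),
         "10x" = objective_spec(10, dof = 0.02, working_distance = 34, name = "10x"),
         "20x" = objective_spec(20, dof = 0.008, working_distance = 20, name = "20x"))
}

# ---- Z-X-Y Euler kinematics -------------------------------------------

#' Z-X-Y Euler rotation matrix
#'
#' Composes `R = Rz(rz) Rx(rx) Ry(ry)` (angles in degrees), the rotation
#' convention of the instrument's rotation stages. The third column of the
#' matrix is the optical-axis direction.
#'
#' @param rx,ry,rz stage angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_zxy <- function(rx, ry, rz = 0) {
  d2r <- pi / 180
  cx <- cos(rx * d2r); sx <- sin(rx * d2r)
  cy <- cos(ry * d2r); sy <- sin(ry * d2r)
  cz <- cos(rz * d2r); sz <- sin(rz * d2r)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz %*% Rx %*% Ry
}

# maximum tilt from the vertical axis reachable by the rotation stages
TILT_LIMIT_DEG <- 83.3

#' Microscope pose
#'
#' Linear-stage position (mm) and rotation-stage angles (degrees, Z-X-Y
#' Euler convention). The tilt from vertical, `acos` of the third-column
#' z of the Euler matrix, must not exceed 83.3 degrees.
#'
#' @param x,y,z linear stage coordinates, mm.
#' @param rx,ry,rz rotation stage angles, degrees.
#' @return A `microscope_pose` object.
#' @export
microscope_pose <- function(x = 0, y = 0, z = 0, rx = 0, ry = 0, rz = 0) {
  R <- euler_zxy(rx, ry, rz)
  tilt <- acos(clamp(R[3, 3], -1, 1)) * 180 / pi
  if (tilt > TILT_LIMIT_DEG + 1e-9)
    stopf("pose tilt %.2f deg exceeds the %.1f deg stage limit", tilt,
          TILT_LIMIT_DEG)
  structure(list(x = x, y = y, z = z, rx = rx, ry = ry, rz = rz,
                 tilt_deg = tilt),
            class = "microscope_pose")
}

#' @export
print.microscope_pose <- function(x, ...) {
  cat(sprintf(
    "microscope_pose: xyz (%.3f, %.3f, %.3f) mm, r (%.2f, %.2f, %.2f) deg, tilt %.2f deg\n",
    x$x, x$y, x$z, x$rx, x$ry, x$rz, x$tilt_deg))
  invisible(x)
}

# rx, ry solving third column of Rz(0) Rx(rx) Ry(ry) == n (unit, nz > 0
# not required). Third column is (sin ry, -sin rx cos ry, cos rx cos ry).
angles_from_normal <- function(n) {
  n <- unname(normalize(n))
  ry <- atan2(n[1], sqrt(n[2]^2 + n[3]^2)) * 180 / pi
  rx <- atan2(-n[2], n[3]) * 180 / pi
  c(rx = rx, ry = ry)
}

# ---- grid decomposition ------------------------------------------------

# Four tangent step directions at a point with normal n: the +/- x and
# +/- y axes projected onto the tangent plane. When n is (near) parallel
# to an axis the whole set degrades to an orthonormal tangent pair derived
# from the axis of smallest |n| component (deterministic).
tangent_directions <- function(n) {
  n <- normalize(n)
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  proj <- axes - outer(drop(axes %*% n), n)
  lens <- row_norms(proj)
  if (any(lens < 1e-8)) {
    a <- diag(3)[, which.min(abs(n))]
    t1 <- normalize(a - sum(a * n) * n)
    t2 <- cross3(n, t1)
    rbind(t1, -t1, t2, -t2)
  } else {
    proj / lens
  }
}

grid_members <- function(mesh, center, normal, l) {
  dirs <- tangent_directions(normal)
  u <- dirs[1, ]; v <- cross3(normal, u)
  rel <- sweep(mesh$vertices, 2, center)
  du_ <- rel %*% u; dv <- rel %*% v
  which(abs(du_) <= l / 2 + 1e-12 & abs(dv) <= l / 2 + 1e-12)
}

new_scan_grid <- function(id, center_pt, avg_normal, l, members, mesh) {
  elev <- mesh$vertices[members, , drop = FALSE] %*% avg_normal
  structure(list(id = id, center = center_pt, avg_normal = avg_normal,
                 grid_length = l, members = members,
                 z_lo = min(elev), z_hi = max(elev)),
            class = "scan_grid")
}

#' Decompose a mesh into FOV-sized scan grids
#'
#' Breadth-first propagation from the surface centroid. At each accepted
#' grid center the local tangent plane is estimated from the k nearest
#' vertices; candidate neighbor centers are placed `overlap_factor * l`
#' along the four tangent directions (the coordinate axes projected onto
#' the tangent plane), snapped back to the surface, merged with existing
#' centers closer than `0.5 * overlap_factor * l`, and discarded when they
#' contribute no new member vertices (mesh-boundary termination). A final
#' sweep seeds extra grids at any vertices left uncovered so that every
#' mesh vertex belongs to at least one grid.
#'
#' @param mesh a [surface_mesh].
#' @param fov_length grid edge length `l`, mm (the microscope FOV edge;
#'   see [compute_fov]).
#' @param overlap_factor center-to-center spacing as a fraction of `l`;
#'   default 0.8 (about 20 percent FOV overlap).
#' @param k neighborhood size for local tangent-plane fits.
#' @return List of `scan_grid` objects (id, center [surface_point],
#'   avg_normal, grid_length, members, z_lo/z_hi elevation extremes).
#' @export
plan_grids <- function(mesh, fov_length, overlap_factor = 0.8, k = 12L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is_scalar_num(fov_length) || fov_length <= 0)
    stopf("fov_length must be > 0")
  if (overlap_factor <= 0 || overlap_factor > 1)
    stopf("overlap_factor must be in (0, 1]")
  l <- fov_length
  step <- overlap_factor * l
  merge_r <- 0.5 * overlap_factor * l
  k <- min(k, nrow(mesh$vertices))

  start <- mesh_centroid(mesh)
  centers <- matrix(start$position, 1, 3)
  grids <- list()
  covered <- rep(FALSE, nrow(mesh$vertices))

  add_grid <- function(pos) {
    n_loc <- tryCatch(local_normal(mesh, pos, k), error = function(e) NULL)
    if (is.null(n_loc)) return(NULL)
    mem <- grid_members(mesh, pos, n_loc, l)
    if (length(mem) == 0L) return(NULL)
    avg_n <- colMeans(mesh$normals[mem, , drop = FALSE])
    if (vnorm(avg_n) < 1e-12) avg_n <- n_loc else avg_n <- normalize(avg_n)
    id <- length(grids) + 1L
    g <- new_scan_grid(id, surface_point(pos, n_loc), avg_n, l, mem, mesh)
    grids[[id]] <<- g
    covered[mem] <<- TRUE
    g
  }

  g0 <- add_grid(start$position)
  if (is.null(g0)) stopf("could not seed a grid at the mesh centroid")
  queue <- list(g0)
  while (length(queue) > 0L) {
    g <- queue[[1]]; queue <- queue[-1]
    dirs <- tangent_directions(local_normal(mesh, g$center$position, k))
    for (d in seq_len(4)) {
      cand <- g$center$position + step * dirs[d, ]
      snap <- closest_point_on_mesh(mesh, cand)$position
      dists <- row_norms(sweep(centers, 2, snap))
      if (min(dists) < merge_r) next           # duplicate suppression
      n_loc <- tryCatch(local_normal(mesh, snap, k), error = function(e) NULL)
      if (is.null(n_loc)) next
      mem <- grid_members(mesh, snap, n_loc, l)
      if (!any(!covered[mem])) next            # boundary: nothing new
      centers <- rbind(centers, snap)
      gn <- add_grid(snap)
      if (!is.null(gn)) queue[[length(queue) + 1L]] <- gn
    }
  }
  # coverage guarantee: seed grids at any remaining uncovered vertices
  while (any(!covered)) {
    idx <- which(!covered)
    # deterministic pick: uncovered vertex farthest from existing centers
    dmin <- vapply(idx, function(i) {
      min(row_norms(sweep(centers, 2, mesh$vertices[i, ])))
    }, numeric(1))
    pos <- mesh$vertices[idx[which.max(dmin)], ]
    centers <- rbind(centers, pos)
    if (is.null(add_grid(pos))) covered[idx[which.max(dmin)]] <- TRUE
  }
  grids
}

#' Microscope pose for a scan grid
#'
#' The Z-X-Y Euler angles whose rotation-matrix third column equals the
#' grid's averaged normal (closed form), with the linear stages placing
#' the optical axis through the grid center at working distance. Errors
#' if the required tilt exceeds the 83.3-degree stage limit.
#'
#' @param grid a `scan_grid`.
#' @param objective an [objective_spec].
#' @return A [microscope_pose].
#' @export
grid_pose <- function(grid, objective) {
  stopifnot(inherits(grid, "scan_grid"), inherits(objective, "objective_spec"))
  n <- grid$avg_normal
  tilt <- acos(clamp(n[3], -1, 1)) * 180 / pi
  if (tilt > TILT_LIMIT_DEG)
    stopf("grid %d requires tilt %.1f deg, beyond the %.1f deg limit",
          grid$id, tilt, TILT_LIMIT_DEG)
  ang <- angles_from_normal(n)
  pos <- grid$center$position + objective$working_distance * n
  microscope_pose(pos[1], pos[2], pos[3], unname(ang["rx"]),
                  unname(ang["ry"]), 0)
}

#' Elevation schedule for a scan grid
#'
#' Evenly spaced focus elevations along the grid's averaged normal,
#' covering the member elevation range padded by `pad` on both sides, at
#' steps no larger than the objective depth of field. The frame count is
#' clamped to the 10-30 range, re-spacing evenly when clamped.
#'
#' @param grid a `scan_grid`.
#' @param objective an [objective_spec].
#' @param pad mm added below the lowest and above the highest member
#'   elevation; default 0.2 mm.
#' @return Strictly increasing numeric vector of elevations (mm, measured
#'   along the grid normal).
#' @export
elevation_schedule <- function(grid, objective, pad = 0.2) {
  stopifnot(inherits(grid, "scan_grid"), inherits(objective, "objective_spec"))
  lo <- grid$z_lo - pad
  hi <- grid$z_hi + pad
  span <- hi - lo
  n <- ceiling(span / objective$dof) + 1L
  n <- clamp(n, 10L, 30L)
  seq(lo, hi, length.out = n)
}

#' Order the scan path over grids
#'
#' Greedy nearest-neighbor tour starting at the first (centroid) grid,
#' with step cost `|drx| + |dry| + 0.01 * ||dxyz||` (degrees; the small
#' Euclidean term breaks ties). The resulting tour never costs more than
#' visiting the grids in input order.
#'
#' @param grids list of `scan_grid`.
#' @param poses list of [microscope_pose], aligned with `grids`.
#' @param schedules optional list of elevation vectors, aligned with
#'   `grids`.
#' @return A `trajectory` object: ordered list of entries
#'   `(grid_id, pose, elevations)` plus the total rotation cost.
#' @export
order_path <- function(grids, poses, schedules = NULL) {
  n <- length(grids)
  if (n == 0L) stopf("no grids to order")
  if (length(poses) != n) stopf("grids and poses differ in length")
  if (!is.null(schedules) && length(schedules) != n)
    stopf("grids and schedules differ in length")
  cost <- function(a, b) {
    abs(a$rx - b$rx) + abs(a$ry - b$ry) +
      0.01 * sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  }
  visited <- rep(FALSE, n)
  order_idx <- integer(n)
  order_idx[1] <- 1L
  visited[1] <- TRUE
  for (s in seq_len(n - 1L)) {
    cur <- order_idx[s]
    rem <- which(!visited)
    costs <- vapply(rem, function(j) cost(poses[[cur]], poses[[j]]), numeric(1))
    nxt <- rem[which.min(costs)]
    order_idx[s + 1L] <- nxt
    visited[nxt] <- TRUE
  }
  tour_cost <- function(idx) {
    if (length(idx) < 2L) return(0)
    sum(vapply(seq_len(length(idx) - 1L), function(i)
      cost(poses[[idx[i]]], poses[[idx[i + 1L]]]), numeric(1)))
  }
  greedy <- tour_cost(order_idx)
  if (greedy > tour_cost(seq_len(n)) + 1e-12) order_idx <- seq_len(n)
  entries <- lapply(order_idx, function(i) {
    list(grid_id = grids[[i]]$id, pose = poses[[i]],
         elevations = if (is.null(schedules)) NULL else schedules[[i]])
  })
  structure(list(entries = entries, order = order_idx,
                 total_cost = tour_cost(order_idx)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d grids, rotation cost %.3f\n",
              length(x$entries), x$total_cost))
  invisible(x)
}

#' Confine a pose to quadrant I by sample rotation
#'
#' Sets the R_z stage angle to the multiple of 90 degrees that maps the
#' pose's (x, y) target into quadrant I (x >= 0, y >= 0) when the sample
#' frame is rotated by `-rz`, so the microscope always works in a single
#' quadrant of the stage plane.
#'
#' @param pose a [microscope_pose].
#' @return The pose with `rz` set.
#' @export
confine_quadrant <- function(pose) {
  stopifnot(inherits(pose, "microscope_pose"))
  tol <- 1e-12
  for (rz in c(0, 90, 180, 270)) {
    th <- -rz * pi / 180
    xr <- cos(th) * pose$x - sin(th) * pose$y
    yr <- sin(th) * pose$x + cos(th) * pose$y
    if (xr >= -tol && yr >= -tol) {
      pose$rz <- rz
      return(pose)
    }
  }
  pose$rz <- 0
  pose
}

#' Plan a complete scan trajectory
#'
#' Convenience wrapper: [plan_grids], [grid_pose], [elevation_schedule],
#' [confine_quadrant] and [order_path] in sequence.
#'
#' @inheritParams plan_grids
#' @param objective an [objective_spec].
#' @param pad elevation padding, mm.
#' @return A `trajectory` with the planned grids attached as
#'   `attr(, "grids")`.
#' @export
plan_trajectory <- function(mesh, objective, fov_length,
                            overlap_factor = 0.8, pad = 0.2) {
  grids <- plan_grids(mesh, fov_length, overlap_factor)
  poses <- lapply(grids, function(g) confine_quadrant(grid_pose(g, objective)))
  scheds <- lapply(grids, elevation_schedule, objective = objective, pad = pad)
  traj <- order_path(grids, poses, scheds)
  attr(traj, "grids") <- grids
  traj
}

#' Serialize a trajectory to JSON
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  entries <- lapply(traj$entries, function(e) {
    list(grid_id = e$grid_id,
         pose = list(x = e$pose$x, y = e$pose$y, z = e$pose$z,
                     rx = e$pose$rx, ry = e$pose$ry, rz = e$pose$rz),
         elevations = e$elevations)
  })
  jsonlite::write_json(list(n_grids = length(entries),
                            total_rotation_cost = traj$total_cost,
                            entries = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
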