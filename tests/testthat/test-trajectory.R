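test_that("a mesh smaller than the FOV yields a single grid at the centroid", {
  plane <- make_surface("plane", extent = 2, n = 6)
  grids <- plan_grids(plane, fov_length = 4.608)
  expect_length(grids, 1L)
  expect_equal(grids[[1]]$center$position, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sort(grids[[1]]$members), seq_len(nrow(plane$vertices)))
})

test_that("flat-plane grids sit exactly 0.8 l apart and cover every vertex", {
  l <- 4.608
  plane <- make_surface("plane", extent = 10, n = 25)
  grids <- plan_grids(plane, l)
  centers <- t(vapply(grids, function(g) g$center$position, numeric(3)))
  xs <- sort(unique(round(centers[, 1], 9)))
  expect_equal(diff(xs), rep(0.8 * l, length(xs) - 1), tolerance = 1e-9)
  ys <- sort(unique(round(centers[, 2], 9)))
  expect_equal(diff(ys), rep(0.8 * l, length(ys) - 1), tolerance = 1e-9)
  # brute-force coverage: every vertex inside some l x l square
  covered <- rep(FALSE, nrow(plane$vertices))
  for (g in grids) covered[g$members] <- TRUE
  expect_true(all(covered))
  for (i in seq_len(nrow(plane$vertices))) {
    d <- abs(sweep(centers[, 1:2, drop = FALSE], 2, plane$vertices[i, 1:2]))
    expect_true(any(d[, 1] <= l / 2 + 1e-9 & d[, 2] <= l / 2 + 1e-9))
  }
})

test_that("hemisphere planning keeps centers on-surface and covers all vertices", {
  l <- 4.608
  hemi <- make_surface("hemisphere", radius = 7.5, n = 24)
  grids <- plan_grids(hemi, l)
  centers <- t(vapply(grids, function(g) g$center$position, numeric(3)))
  for (k in seq_len(nrow(centers)))
    expect_lt(closest_point_on_mesh(hemi, centers[k, ])$distance, 1e-6)
  # chordal distance from every vertex to its nearest center
  covered <- rep(FALSE, nrow(hemi$vertices))
  for (g in grids) covered[g$members] <- TRUE
  expect_true(all(covered))
  dmin <- vapply(seq_len(nrow(hemi$vertices)), function(i)
    min(musescan:::row_norms(sweep(centers, 2, hemi$vertices[i, ]))),
    numeric(1))
  expect_lt(max(dmin), l / sqrt(2))
})

test_that("planning is bit-reproducible", {
  bumpy <- make_surface("bumpy", extent = 10, amplitude = 1, n = 20, seed = 5)
  g1 <- plan_grids(bumpy, 4.608)
  g2 <- plan_grids(bumpy, 4.608)
  expect_identical(g1, g2)
})

test_that("grid poses reproduce the grid normal in the Euler third column", {
  obj <- objective_preset("5x")
  hemi <- make_surface("hemisphere", radius = 7.5, n = 24)
  grids <- plan_grids(hemi, 4.608)
  for (g in grids) {
    pose <- grid_pose(g, obj)
    R <- euler_zxy(pose$rx, pose$ry, pose$rz)
    expect_lt(max(abs(R[, 3] - g$avg_normal)), 1e-10)
  }
})

test_that("vertical and tilted viewing angles solve in closed form", {
  obj <- objective_preset("5x")
  g <- plan_grids(make_surface("plane", extent = 2, n = 6), 4.608)[[1]]
  pose <- grid_pose(g, obj)
  expect_equal(c(pose$rx, pose$ry), c(0, 0))
  # 45-degree normal: matrix round trip to 1e-12
  g45 <- g
  g45$avg_normal <- c(0, sin(pi / 4), cos(pi / 4))
  p45 <- grid_pose(g45, obj)
  R <- euler_zxy(p45$rx, p45$ry, p45$rz)
  expect_lt(max(abs(R[, 3] - g45$avg_normal)), 1e-12)
  # beyond the 83.3-degree stage limit
  g85 <- g
  g85$avg_normal <- c(0, sin(85 * pi / 180), cos(85 * pi / 180))
  expect_error(grid_pose(g85, obj), "83.3")
})

test_that("elevation schedules respect the depth of field and the 10-30 clamp", {
  obj <- objective_spec(5, dof = 0.05)
  g <- plan_grids(make_surface("plane", extent = 2, n = 6), 4.608)[[1]]
  # flat grid: span 0 + 2 * 0.2 pad = 0.4 -> 9 computed frames -> clamp 10
  expect_equal(g$z_hi - g$z_lo, 0)
  e <- elevation_schedule(g, obj, pad = 0.2)
  expect_length(e, 10L)
  expect_equal(range(e), c(-0.2, 0.2))
  # span 1.0 -> 1.4 / 0.05 -> 29 frames, inside the clamp
  g2 <- g; g2$z_lo <- 0; g2$z_hi <- 1
  e2 <- elevation_schedule(g2, obj, 0.2)
  expect_length(e2, 29L)
  # span 4.0 -> 4.4 total -> clamped to 30, re-spaced evenly at 4.4 / 29
  g3 <- g; g3$z_lo <- 0; g3$z_hi <- 4
  e3 <- elevation_schedule(g3, obj, 0.2)
  expect_length(e3, 30L)
  expect_equal(diff(e3), rep(4.4 / 29, 29), tolerance = 1e-12)
  # all elevations within the padded range, strictly increasing
  expect_true(all(diff(e3) > 0))
  expect_true(all(e3 >= g3$z_lo - 0.2 - 1e-9 & e3 <= g3$z_hi + 0.2 + 1e-9))
})

test_that("greedy path ordering never beats the exhaustive optimum nor loses to input order", {
  obj <- objective_preset("5x")
  plane <- make_surface("plane", extent = 12, n = 20)
  grids <- plan_grids(plane, 4.608)
  grids <- grids[seq_len(min(8L, length(grids)))]
  poses <- lapply(grids, function(g) {
    p <- grid_pose(g, obj)
    # perturb rotations deterministically so the cost field is non-trivial
    p$rx <- p$rx + g$id %% 3; p$ry <- p$ry + g$id %% 5
    p
  })
  traj <- order_path(grids, poses)
  greedy_cost <- path_cost(poses, traj$order)
  expect_equal(traj$total_cost, greedy_cost, tolerance = 1e-12)
  expect_lte(greedy_cost, path_cost(poses, seq_along(grids)) + 1e-12)
  # exhaustive optimum over all orders starting at grid 1
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- min(vapply(perms(seq_along(grids)[-1]), function(p)
    path_cost(poses, c(1L, p)), numeric(1)))
  expect_gte(greedy_cost, best - 1e-12)
  # single grid and zero-cost fields
  expect_length(order_path(grids[1], poses[1])$entries, 1L)
  same <- lapply(seq_along(grids), function(i) poses[[1]])
  expect_equal(order_path(grids, same)$total_cost,
               0.01 * 0 + path_cost(same, order_path(grids, same)$order))
  expect_error(order_path(grids, poses[-1]), "differ")
})

test_that("quadrant confinement maps the target into quadrant I with rz multiples of 90", {
  mk <- function(x, y) microscope_pose(x, y, 34)
  expect_equal(confine_quadrant(mk(1, 1))$rz, 0)
  expect_equal(confine_quadrant(mk(-1, 1))$rz, 90)
  expect_equal(confine_quadrant(mk(0, 0))$rz, 0)
  for (ang in seq(5, 355, by = 33)) {
    p <- confine_quadrant(mk(cos(ang * pi / 180), sin(ang * pi / 180)))
    th <- -p$rz * pi / 180
    xr <- cos(th) * p$x - sin(th) * p$y
    yr <- sin(th) * p$x + cos(th) * p$y
    expect_true(xr >= -1e-9 && yr >= -1e-9)
    expect_true(p$rz %in% c(0, 90, 180, 270))
  }
})

test_that("pose tilt limit is enforced at construction", {
  expect_error(microscope_pose(rx = 85), "83.3")
  expect_silent(microscope_pose(rx = 80))
})

test_that("trajectories serialize to JSON and back", {
  obj <- objective_preset("5x")
  plane <- make_surface("plane", extent = 10, n = 15)
  traj <- plan_trajectory(plane, obj, 4.608)
  path <- withr::local_tempfile(fileext = ".json")
  write_trajectory(traj, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$n_grids, length(traj$entries))
  expect_equal(length(parsed$entries$grid_id), length(traj$entries))
  ids <- vapply(traj$entries, `[[`, integer(1), "grid_id")
  expect_setequal(parsed$entries$grid_id, ids)
  expect_true(all(vapply(traj$entries, function(e)
    all(diff(e$elevations) > 0), logical(1))))
})

test_that("planning works end to end on meshes loaded from disk", {
  mesh <- make_surface("bumpy", extent = 10, amplitude = 1, n = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh, path)
  traj <- plan_trajectory(load_mesh(path), objective_preset("5x"), 4.608)
  expect_s3_class(traj, "trajectory")
  expect_gt(length(traj$entries), 1L)
  expect_true(all(vapply(traj$entries, function(e)
    is.finite(e$pose$rx) && is.finite(e$pose$ry), logical(1))))
})
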