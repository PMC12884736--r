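test_that("tile projection matches the closed-form pixel map and inverts exactly", {
  A <- intrinsic_matrix(5)
  H <- compose_homography(A, extrinsic_pose())
  mesh <- make_surface("plane", extent = 4, n = 10)
  pose <- microscope_pose(0, 0, 34)
  tile <- matrix(0, 512, 512)
  proj <- project_tile(tile, pose, H, mesh, center = c(0, 0, 0))
  expect_true(all(proj$assigned))
  scale <- 512 / 5120
  for (i in c(3, 57, 120)) {
    vids <- mesh$faces[i, ]
    expected <- t(vapply(vids, function(k)
      (mesh$vertices[k, 1:2] * 1000 * 5 / 4.5 + 2560) * scale, numeric(2)))
    expect_lt(max(abs(proj$uv[[i]] - expected)), 1e-6)
    back <- unproject_pixel(proj$uv[[i]], proj, pose, H)
    expect_lt(max(abs(back[, 1:2] - mesh$vertices[vids, 1:2])), 1e-9)
  }
})

test_that("facets outside the tile footprint stay unassigned", {
  A <- intrinsic_matrix(5)
  H <- compose_homography(A, extrinsic_pose())
  mesh <- make_surface("plane", extent = 20, n = 20)  # larger than one FOV
  proj <- project_tile(matrix(0, 256, 256), microscope_pose(0, 0, 34), H,
                       mesh, center = c(0, 0, 0))
  expect_true(any(proj$assigned))
  expect_true(any(!proj$assigned))
  fc <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
           mesh$vertices[mesh$faces[, 3], ]) / 3
  far <- musescan:::row_norms(fc[, 1:2, drop = FALSE]) > 4.608
  expect_true(all(!proj$assigned[far]))
})

test_that("projected area forshortens by cos(45) on a tilted plane", {
  A <- intrinsic_matrix(5)
  H <- compose_homography(A, extrinsic_pose())
  # plane tilted 45 degrees about x, viewed vertically
  flat <- make_surface("plane", extent = 2, n = 8)
  tilted <- flat
  tilted$vertices <- flat$vertices %*% t(euler_zxy(45, 0, 0))
  tilted$normals <- flat$normals %*% t(euler_zxy(45, 0, 0))
  pose <- microscope_pose(0, 0, 34)
  pr_f <- project_tile(matrix(0, 512, 512), pose, H, flat, center = c(0, 0, 0))
  pr_t <- project_tile(matrix(0, 512, 512), pose, H, tilted, center = c(0, 0, 0))
  tri_area <- function(uv) abs((uv[2, 1] - uv[1, 1]) * (uv[3, 2] - uv[1, 2]) -
                                 (uv[3, 1] - uv[1, 1]) * (uv[2, 2] - uv[1, 2])) / 2
  i <- which(pr_f$assigned & pr_t$assigned)[1]
  ratio <- tri_area(pr_t$uv[[i]]) / tri_area(pr_f$uv[[i]])
  expect_equal(ratio, cos(pi / 4), tolerance = 0.01)
})

test_that("view selection is exact when decoupled and near-optimal on small graphs", {
  mesh <- make_surface("plane", extent = 2, n = 3)   # 8 facets
  nf <- nrow(mesh$faces)
  ax1 <- musescan:::normalize(c(0.2, 0, 1))
  ax2 <- musescan:::normalize(c(-0.3, 0.1, 1))
  cands <- lapply(seq_len(nf), function(i)
    list(list(tile_id = 1L, view_axis = ax1),
         list(tile_id = 2L, view_axis = ax2)))
  # single candidate per facet
  single <- lapply(seq_len(nf), function(i) cands[[i]][1])
  expect_true(all(select_views(mesh, single, 0.5)$labels == 1L))
  # lambda = 0: exact per-facet argmin of the unary cost
  sel0 <- select_views(mesh, cands, lambda = 0)
  fn <- musescan:::facet_normals_raw(mesh$vertices, mesh$faces)
  fn <- fn / musescan:::row_norms(fn)
  un <- cbind(1 - fn %*% ax1, 1 - fn %*% ax2)
  expect_equal(sel0$labels, unname(max.col(-un, ties.method = "first")))
  # lambda = 0.5: within 5% of the exhaustive optimum over 2^8 labelings
  sel <- select_views(mesh, cands, lambda = 0.5)
  expect_true(all(diff(sel$energy_trace) <= 1e-12))
  edges <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
                 mesh$faces[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  prs <- Filter(function(g) length(g) == 2, split(rep(seq_len(nf), 3), ekey))
  best <- Inf
  for (m in 0:(2^nf - 1)) {
    lab <- as.integer(intToBits(m))[seq_len(nf)] + 1L
    e <- sum(un[cbind(seq_len(nf), lab)]) +
      0.5 * sum(vapply(prs, function(g) lab[g[1]] != lab[g[2]], logical(1)))
    best <- min(best, e)
  }
  expect_lte(sel$energy, 1.05 * best + 1e-12)
  # facets with no candidates stay unassigned
  none <- cands; none[[1]] <- list()
  expect_true(is.na(select_views(mesh, none, 0.5)$labels[1]))
})

test_that("Poisson blending removes seam steps and preserves interior gradients", {
  # two patches cut from one continuous field, sharing the seam column
  big <- musescan:::with_seed(2, matrix(100 + rnorm(32 * 63, 0, 2), 32))
  base <- big[, 1:32]
  right <- big[, 32:63]
  atlas <- list(base, right + 30)
  seams <- list(list(a = 1, side_a = "right", b = 2, side_b = "left"))
  pre <- seam_step(atlas, seams)
  expect_gt(pre, 25)
  blended <- blend_brightness(atlas, seams)
  expect_lt(seam_step(blended, seams), 3)
  expect_lt(seam_step(blended, seams), 0.1 * pre)
  # interior Laplacian equals the source Laplacian (gradient preservation)
  interior <- 3:30
  expect_lt(max(abs(musescan:::lap5(blended[[1]])[interior, interior] -
                      musescan:::lap5(base)[interior, interior])), 1e-6)
  # identical-brightness tiles are left untouched
  same <- blend_brightness(list(base, right),
                           list(list(a = 1, side_a = "right",
                                     b = 2, side_b = "left")))
  expect_lt(max(abs(same[[1]] - base)), 1)
  expect_lt(max(abs(same[[2]] - right)), 1)
})

test_that("intensity inversion is an involution and reverses ramps", {
  img <- checkerboard_image(32)
  expect_equal(invert_intensity(invert_intensity(img)), img)
  expect_equal(invert_intensity(matrix(40, 2, 2)), matrix(215, 2, 2))
  ramp <- matrix(seq(10, 240, length.out = 50), 1)
  expect_true(all(diff(invert_intensity(ramp)[1, ]) < 0))
})

test_that("the color moment loss follows the printed formula", {
  z <- array(0, c(8, 8, 3))
  o <- array(1, c(8, 8, 3))
  expect_equal(color_moment_loss(z, z), 0)
  expect_equal(color_moment_loss(z, o), 1)   # means differ by 1, stds equal
  a <- musescan:::with_seed(4, array(runif(8 * 8 * 3), c(8, 8, 3)))
  b <- musescan:::with_seed(5, array(runif(8 * 8 * 3), c(8, 8, 3)))
  expect_equal(color_moment_loss(a, b), color_moment_loss(b, a))
  # invariant to spatial permutation within each channel
  perm <- musescan:::with_seed(6, sample(64))
  ap <- a
  for (k in 1:3) ap[, , k] <- matrix(as.vector(a[, , k])[perm], 8)
  expect_equal(color_moment_loss(ap, b), color_moment_loss(a, b))
  expect_error(color_moment_loss(a, a[, , 1:2]), "channel")
  # sum-reduction switch scales the loss by the channel count
  expect_equal(color_moment_loss(z, o, reduce = "sum"), 3)
})

test_that("pseudo-H&E rendering is white at zero and darkens monotonically", {
  zero <- matrix(0, 4, 4)
  white <- pseudo_he_render(zero, zero)
  expect_equal(as.vector(white[1, 1, ]), c(255, 255, 255))
  nuc <- pseudo_he_render(matrix(255, 4, 4), zero)
  rgb <- nuc[1, 1, ]
  expect_true(rgb[3] >= rgb[1] && rgb[1] > rgb[2])  # hematoxylin: B >= R > G
  zero2 <- matrix(0, 2, 2)
  for (lvl in seq(0, 200, by = 50)) {
    a <- pseudo_he_render(matrix(lvl, 2, 2), zero2)[1, 1, ]
    b <- pseudo_he_render(matrix(lvl + 50, 2, 2), zero2)[1, 1, ]
    expect_true(all(b <= a))
  }
  expect_error(pseudo_he_render(zero, matrix(0, 2, 2)), "shapes")
})

test_that("painting, imaging and synthesis round-trip a surface pattern", {
  # smooth pattern painted on the surface; full-FOV tiles at reduced
  # resolution; texture atlas rasterized top-down and compared to truth
  pattern <- function(x, y) 128 + 100 * sin(0.8 * x) * cos(0.6 * y)
  obj <- objective_preset("5x")
  A <- intrinsic_matrix(5)
  H <- compose_homography(A, extrinsic_pose())
  for (shape in c("plane", "hemisphere")) {
    mesh <- if (shape == "plane") make_surface("plane", extent = 8, n = 30)
    else make_surface("hemisphere", radius = 4, n = 30)
    grids <- plan_grids(mesh, 4.608)
    tiles <- list(); projs <- list()
    for (i in seq_along(grids)) {
      g <- grids[[i]]
      pose <- grid_pose(g, obj)
      tiles[[i]] <- render_tile(pattern, pose, H, g$center$position,
                                tile_px = 256L, pixel_N = 5120L)
      projs[[i]] <- project_tile(tiles[[i]], pose, H, mesh,
                                 center = g$center$position, pixel_N = 5120L)
    }
    cands <- lapply(seq_len(nrow(mesh$faces)), function(fi) {
      hits <- which(vapply(projs, function(p) p$assigned[fi], logical(1)))
      lapply(hits, function(ti)
        list(tile_id = ti, view_axis = projs[[ti]]$view_axis))
    })
    sel <- select_views(mesh, cands, lambda = 0.5)
    ts <- texture_surface(mesh, tiles, projs, sel$labels)
    ras <- rasterize_texture(ts, px_per_mm = 10)
    nxp <- ncol(ras$image); nyp <- nrow(ras$image)
    gx <- ras$x0 + (seq_len(nxp) - 1) / ras$px_per_mm
    gy <- ras$y0 + (seq_len(nyp) - 1) / ras$px_per_mm
    truth <- outer(gy, gx, function(yy, xx) pattern(xx, yy))
    ok <- !is.na(ras$image)
    expect_gt(mean(ok), 0.5)
    ncc <- cor(ras$image[ok], truth[ok])
    expect_gte(ncc, 0.95)
  }
})
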