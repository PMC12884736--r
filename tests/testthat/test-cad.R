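test_that("image tiling discards partial edges and reports the physical footprint", {
  img <- matrix(runif(512 * 512), 512)
  tiles <- tile_image(img, size = 128)
  expect_length(tiles, 16L)
  expect_true(all(vapply(tiles, function(s) all(dim(s$patch) == 128), logical(1))))
  expect_length(tile_image(matrix(0, 130, 130), 128), 1L)
  expect_error(tile_image(matrix(0, 100, 100), 128), "smaller")
  # 128 px at 5x: edge = 128 * 4.5 / 5 um = 0.1152 mm, about 0.12 mm
  expect_equal(tiles[[1]]$edge_mm, 0.1152)
  expect_equal(round(tiles[[1]]$edge_mm, 2), 0.12)
})

test_that("section-distance filtering keeps the 0.5 mm band", {
  mk <- function(x, y) {
    s <- tile_image(matrix(0, 128, 128), 128)[[1]]
    s$surface_position <- c(x, y)
    s
  }
  line <- rbind(c(0, 0), c(10, 0))
  subs <- list(mk(5, 0), mk(5, 0.49), mk(5, 0.51), mk(2, -0.3))
  kept <- filter_by_section_distance(subs, line, 0.5)
  pos <- t(vapply(kept, `[[`, numeric(2), "surface_position"))
  expect_equal(nrow(pos), 3L)
  expect_false(any(pos[, 2] > 0.5))
  expect_true(all(vapply(kept, function(s) !is.na(s$section_distance),
                         logical(1))))
  expect_warning(filter_by_section_distance(list(mk(5, 3)), line, 0.5),
                 "no subimages")
})

test_that("k-means segmentation separates two-level and mixture images", {
  fix <- disk_image(rbind(c(30, 30), c(80, 90), c(100, 40)), radius = 10)
  seg <- segment_nuclei(fix$image)
  expect_identical(seg$mask, fix$mask)
  expect_equal(seg$count, 3L)
  expect_equal(seg$areas, rep(317, 3))   # rasterized disk pixel count
  # Gaussian mixture: misclassification under 2%
  truth <- musescan:::with_seed(5, matrix(runif(128^2) < 0.2, 128))
  img <- matrix(60, 128, 128)
  img[truth] <- 180
  img <- img + musescan:::with_seed(6, matrix(rnorm(128^2, 0, 15), 128))
  seg2 <- segment_nuclei(img)
  expect_lt(mean(seg2$mask != truth), 0.02)
  # constant image signals an empty mask
  seg3 <- segment_nuclei(matrix(5, 64, 64))
  expect_true(seg3$empty)
  expect_equal(sum(seg3$mask), 0L)
})

test_that("8-connected labeling joins diagonals and counts areas", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE    # diagonal chain: one component
  lab <- label_components(m)
  expect_equal(max(lab), 1L)
  m[5, 5] <- TRUE
  expect_equal(max(label_components(m)), 2L)
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0L)
})

test_that("feature extraction matches hand-counted fixtures", {
  fix <- disk_image(rbind(c(30, 30), c(80, 90), c(100, 40)), radius = 10)
  fv <- extract_features(fix$image)
  expect_equal(unname(fv["nc_ratio"]), 3 * 317 / 16384, tolerance = 1e-12)
  expect_equal(unname(fv["avg_nuclear_intensity"]), 200)
  expect_equal(unname(fv["mean_nuclear_area"]), 317)
  expect_equal(unname(fv["std_nuclear_area"]), 0)
  expect_false(attr(fv, "excluded"))
  # single component: zero area spread
  one <- disk_image(matrix(c(60, 60), 1), radius = 8)
  expect_equal(unname(extract_features(one$image)["std_nuclear_area"]), 0)
  # empty mask: zero vector, flagged
  fv0 <- extract_features(matrix(7, 128, 128))
  expect_equal(as.numeric(fv0), c(0, 0, 0, 0))
  expect_true(attr(fv0, "excluded"))
})

test_that("artifact exclusion applies the 10 percent overlap rule", {
  img <- matrix(0, 256, 256)
  subs <- tile_image(img, 128)
  none <- matrix(FALSE, 256, 256)
  expect_length(exclude_artifacts(subs, none), 4L)
  full <- none; full[1:128, 1:128] <- TRUE       # tile 1 fully inside
  expect_length(exclude_artifacts(subs, full), 3L)
  m5 <- none; m5[1:128, 1:7] <- TRUE             # ~5% of tile 1
  expect_length(exclude_artifacts(subs, m5), 4L)
  m15 <- none; m15[1:128, 1:20] <- TRUE          # ~15% of tile 1
  expect_length(exclude_artifacts(subs, m15), 3L)
  expect_error(exclude_artifacts(subs, matrix(FALSE, 100, 100)), "smaller")
})

test_that("stratified splitting is exact, seeded and exhaustive", {
  labels <- rep(c("positive", "negative"), each = 50)
  idx <- split_dataset(labels, 0.6, seed = 3)
  expect_length(idx$train, 60L)
  expect_length(idx$test, 40L)
  expect_equal(sum(labels[idx$train] == "positive"), 30L)
  expect_equal(sum(labels[idx$test] == "positive"), 20L)
  expect_identical(split_dataset(labels, 0.6, seed = 3), idx)
  for (r in 1:5) {
    labs <- musescan:::with_seed(r, sample(c("positive", "negative"), 37,
                                           replace = TRUE, prob = c(.4, .6)))
    if (min(table(labs)) < 2) next
    ix <- split_dataset(labs, 0.6, seed = r)
    expect_setequal(c(ix$train, ix$test), seq_along(labs))
    expect_length(intersect(ix$train, ix$test), 0L)
  }
  expect_error(split_dataset(rep("positive", 10)), "class")
})

test_that("the logistic fit matches glm and separates separable classes", {
  set.seed(10)
  X <- matrix(rnorm(400 * 3), ncol = 3)
  colnames(X) <- c("a", "b", "c")
  eta <- X %*% c(1.2, -0.7, 0)
  y <- rbinom(400, 1, 1 / (1 + exp(-eta)))
  if (length(unique(y)) == 2) {
    mdl <- train_margin_model(X, y)
    Xs <- scale(X)
    ref <- glm(y ~ Xs, family = binomial())
    expect_equal(unname(mdl$coefficients), unname(coef(ref)),
                 tolerance = 1e-4)
    expect_true(mdl$converged)
  }
  # perfectly separable: training AUC 1
  Xs2 <- cbind(f = c(rnorm(50, -3), rnorm(50, 3)),
               g = rnorm(100), h = rnorm(100), i = rnorm(100))
  ys <- rep(0:1, each = 50)
  mdl2 <- train_margin_model(Xs2, ys)
  expect_equal(roc_curve(predict(mdl2, Xs2), ys)$auc, 1)
  expect_error(train_margin_model(Xs2, rep(1, 100)), "classes")
  expect_error(train_margin_model(cbind(c(NA, 1, 2), 1:3), c(0, 1, 1)),
               "non-finite")
})

test_that("logistic coefficients recover a known generator within Wald intervals", {
  beta_true <- c(2, -1, 0.5, 0)
  set.seed(1)
  X <- matrix(rnorm(5000 * 4), ncol = 4)
  y <- rbinom(5000, 1, 1 / (1 + exp(-(X %*% beta_true))))
  mdl <- train_margin_model(X, y)
  # back-transform to the generator scale (fit is on standardized features)
  b_raw <- mdl$coefficients[-1] / mdl$scale
  se_raw <- mdl$se[-1] / mdl$scale
  for (j in 1:4) {
    expect_gt(beta_true[j], b_raw[j] - 1.96 * se_raw[j])
    expect_lt(beta_true[j], b_raw[j] + 1.96 * se_raw[j])
  }
})

test_that("ROC analysis matches the rank-sum oracle and behaves under nulls", {
  # perfect scores
  y <- rep(c(0, 1), each = 20)
  s <- c(rnorm(20, 0), rnorm(20, 10))
  roc <- roc_curve(s, y)
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  # brute-force Mann-Whitney agreement on small sets, with ties
  musescan:::with_seed(8, {
    for (r in 1:5) {
      n <- sample(20:200, 1)
      yy <- rbinom(n, 1, 0.4)
      if (length(unique(yy)) < 2) next
      ss <- round(rnorm(n, yy), 1)   # rounding induces ties
      expect_equal(roc_curve(ss, yy)$auc, brute_force_auc(ss, yy),
                   tolerance = 1e-12)
      # AUC invariant under strictly increasing transforms
      expect_equal(roc_curve(exp(ss / 2), yy)$auc, roc_curve(ss, yy)$auc)
    }
  })
  # independent scores: AUC near 1/2
  musescan:::with_seed(9, {
    yy <- rep(0:1, 1000)
    ss <- rnorm(2000)
    expect_gt(roc_curve(ss, yy)$auc, 0.47)
    expect_lt(roc_curve(ss, yy)$auc, 0.53)
  })
  # cross-check against pROC on a fixed sample
  musescan:::with_seed(12, {
    yy <- rbinom(300, 1, 0.5)
    ss <- rnorm(300, yy)
    expect_equal(roc_curve(ss, yy)$auc,
                 as.numeric(suppressMessages(pROC::auc(yy, ss))),
                 tolerance = 1e-10)
  })
})

test_that("evaluation reports sensitivity and specificity with Wilson intervals", {
  X <- musescan:::with_seed(21, cbind(f1 = c(rnorm(60, -4), rnorm(60, 4)),
                                      f2 = rnorm(120), f3 = rnorm(120),
                                      f4 = rnorm(120)))
  y <- rep(c("negative", "positive"), each = 60)
  idx <- split_dataset(y, 0.6, seed = 2)
  mdl <- train_margin_model(X[idx$train, ], y[idx$train])
  rep_ <- evaluate_margin_model(mdl, X[idx$test, ], y[idx$test])
  expect_equal(rep_$auc, 1)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)
  expect_length(rep_$per_feature, 4L)
  # Wilson interval agrees with prop.test without continuity correction
  ci <- wilson_ci(45, 50)
  ref <- prop.test(45, 50, correct = FALSE)$conf.int
  expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-9)
  expect_error(evaluate_margin_model(mdl, X[1:5, ], rep("negative", 5)),
               "both classes")
})

test_that("positive-margin areas aggregate 8-connected subimage calls", {
  expect_identical(margin_areas(matrix(FALSE, 4, 4)), numeric(0))
  single <- matrix(FALSE, 4, 4); single[2, 2] <- TRUE
  a1 <- margin_areas(single)
  expect_equal(a1, 0.1152^2)
  expect_equal(round(a1, 4), 0.0133)   # same order as the smallest margins
  block <- matrix(FALSE, 4, 4); block[2:3, 2:3] <- TRUE
  expect_equal(margin_areas(block), 4 * 0.1152^2)
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_length(margin_areas(diag2), 1L)   # diagonal neighbors join
})

test_that("feature tables round-trip through CSV", {
  fix <- disk_image(rbind(c(30, 30), c(90, 90)), radius = 8, n = 256)
  subs <- tile_image(fix$image, 128)
  feats <- lapply(subs, extract_features)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(subs, feats, path)
  df <- read_feature_table(path)
  expect_equal(nrow(df), 4L)
  expect_equal(df$nc_ratio, vapply(feats, function(f) f[["nc_ratio"]],
                                   numeric(1)))
})
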