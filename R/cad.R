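# Computer-aided margin assessment: subimage tiling, k-means nucleus
# segmentation, the four nuclear features, artifact exclusion, dataset
# splitting, the logistic margin model and ROC evaluation.

#' 8-connected component labeling
#'
#' Vectorized minimum-label propagation; deterministic, labels packed
#' 1..n in raster order of first occurrence.
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(Inf, n1, n2)
  lab[mask] <- which(mask)
  if (!any(mask)) return(matrix(0L, n1, n2))
  repeat {
    P <- matrix(Inf, n1 + 2L, n2 + 2L)
    P[2:(n1 + 1L), 2:(n2 + 1L)] <- lab
    nb <- lab
    for (di in -1:1) for (dj in -1:1)
      nb <- pmin(nb, P[(2 + di):(n1 + 1 + di), (2 + dj):(n2 + 1 + dj)])
    nb[!mask] <- Inf
    if (all(nb[mask] == lab[mask])) break
    lab <- nb
  }
  out <- matrix(0L, n1, n2)
  vals <- lab[mask]
  out[mask] <- match(vals, unique(vals))   # packed by first occurrence
  storage.mode(out) <- "integer"
  out
}

#' Tile an image into fixed-size subimages
#'
#' Non-overlapping raster tiling from the top-left; partial edge tiles
#' are discarded. At 5x magnification (du = 4.5 um) the 128-pixel edge
#' corresponds to 0.1152 mm (about 0.12 mm).
#'
#' @param image numeric matrix.
#' @param size tile edge, pixels; default 128.
#' @param pixel_mm physical pixel pitch on the sample, mm (e.g.
#'   `du / m / 1000`); used to attach surface positions.
#' @param origin_mm length-2 surface position (mm) of pixel (0, 0).
#' @param label class label inherited by every tile ("positive",
#'   "negative" or "unknown").
#' @return List of `sub_image` objects: `patch`, `origin` (0-based
#'   row/col), `surface_position` (mm, patch center), `label`,
#'   `excluded`, `section_distance`.
#' @export
tile_image <- function(image, size = 128L, pixel_mm = 4.5 / 5 / 1000,
                       origin_mm = c(0, 0), label = "unknown") {
  if (nrow(image) < size || ncol(image) < size)
    stopf("image (%d x %d) smaller than one %d-pixel tile",
          nrow(image), ncol(image), size)
  nr <- nrow(image) %/% size
  nc <- ncol(image) %/% size
  out <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r0 <- (r - 1L) * size; c0 <- (cc - 1L) * size
    k <- k + 1L
    out[[k]] <- structure(
      list(patch = image[r0 + seq_len(size), c0 + seq_len(size)],
           origin = c(row = r0, col = c0),
           surface_position = c(origin_mm[1] + (c0 + size / 2) * pixel_mm,
                                origin_mm[2] + (r0 + size / 2) * pixel_mm),
           edge_mm = size * pixel_mm,
           label = label, excluded = FALSE,
           section_distance = NA_real_),
      class = "sub_image")
  }
  out
}

# minimum distance from point p to a polyline (n x 2)
point_polyline_distance <- function(p, line) {
  line <- as.matrix(line)
  if (nrow(line) == 1L) return(sqrt(sum((p - line[1, ])^2)))
  a <- line[-nrow(line), , drop = FALSE]
  b <- line[-1, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, -p)   # p - a
  t <- rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-300)
  t <- clamp(t, 0, 1)
  proj <- a + ab * t
  sqrt(min(rowSums(sweep(proj, 2, p)^2)))
}

#' Keep subimages near the sectioning line
#'
#' Only subimages whose surface position lies within `max_dist` of the
#' sectioned-slice polyline are retained (tangent-plane Euclidean
#' distance); the ground-truth labels come from histology on that
#' section, so distant subimages have unreliable labels.
#'
#' @param subimages list of `sub_image`.
#' @param section_line n x 2 polyline, mm.
#' @param max_dist mm; default 0.5.
#' @return Filtered list with `section_distance` set on every element.
#' @export
filter_by_section_distance <- function(subimages, section_line,
                                       max_dist = 0.5) {
  if (length(section_line) == 0L || nrow(as.matrix(section_line)) == 0L)
    stopf("section_line must be non-empty")
  d <- vapply(subimages, function(s)
    point_polyline_distance(s$surface_position, section_line), numeric(1))
  subimages <- Map(function(s, di) { s$section_distance <- di; s },
                   subimages, d)
  keep <- d <= max_dist
  if (!any(keep)) warning("no subimages within the section band")
  subimages[keep]
}

#' Segment nuclei by 2-cluster k-means on intensity
#'
#' Pixels are split into two intensity clusters (deterministic quantile
#' initialization); the brighter cluster is labeled nuclei (fluorescence
#' convention, before intensity inversion). Components are 8-connected.
#'
#' @param subimage a `sub_image` or numeric matrix.
#' @return List: `mask` (logical), `labels` (component matrix),
#'   `areas` (pixels per component), `centroids` (component x/y),
#'   `count`, `empty` (TRUE for constant images, with an empty mask).
#' @export
segment_nuclei <- function(subimage) {
  patch <- if (inherits(subimage, "sub_image")) subimage$patch else subimage
  v <- as.vector(patch)
  if (diff(range(v)) < 1e-12) {
    return(list(mask = matrix(FALSE, nrow(patch), ncol(patch)),
                labels = matrix(0L, nrow(patch), ncol(patch)),
                areas = numeric(0), centroids = NULL, count = 0L,
                empty = TRUE))
  }
  centers <- matrix(quantile(v, c(0.25, 0.75)), ncol = 1)
  if (diff(centers[, 1]) < 1e-12) centers[, 1] <- range(v)
  km <- kmeans(v, centers = centers, iter.max = 50L)
  bright <- which.max(km$centers)
  mask <- matrix(km$cluster == bright, nrow(patch))
  labels <- label_components(mask)
  count <- max(labels)
  areas <- if (count > 0L) tabulate(labels[labels > 0L], count) else numeric(0)
  centroids <- if (count > 0L) {
    ij <- which(labels > 0L, arr.ind = TRUE)
    cbind(x = tapply(ij[, 2], labels[labels > 0L], mean),
          y = tapply(ij[, 1], labels[labels > 0L], mean))
  } else NULL
  list(mask = mask, labels = labels, areas = as.numeric(areas),
       centroids = centroids, count = as.integer(count), empty = FALSE)
}

#' Extract the four margin features from a segmented subimage
#'
#' Nucleocytoplasmic ratio (nucleus pixels / total pixels), average
#' nuclear signal intensity, and mean and standard deviation of nuclear
#' cross-section areas (pixels). An empty mask yields the zero vector
#' with the `excluded` attribute set.
#'
#' @param subimage a `sub_image` or matrix.
#' @param segmentation result of [segment_nuclei]; computed when `NULL`.
#' @return Named numeric length 4 (`nc_ratio`,
#'   `avg_nuclear_intensity`, `mean_nuclear_area`, `std_nuclear_area`)
#'   with attribute `excluded`.
#' @export
extract_features <- function(subimage, segmentation = NULL) {
  patch <- if (inherits(subimage, "sub_image")) subimage$patch else subimage
  if (is.null(segmentation)) segmentation <- segment_nuclei(patch)
  if (segmentation$empty || segmentation$count == 0L) {
    out <- c(nc_ratio = 0, avg_nuclear_intensity = 0,
             mean_nuclear_area = 0, std_nuclear_area = 0)
    attr(out, "excluded") <- TRUE
    return(out)
  }
  areas <- segmentation$areas
  sdv <- if (length(areas) > 1L) sd(areas) else 0
  out <- c(nc_ratio = sum(segmentation$mask) / length(patch),
           avg_nuclear_intensity = mean(patch[segmentation$mask]),
           mean_nuclear_area = mean(areas),
           std_nuclear_area = sdv)
  attr(out, "excluded") <- FALSE
  out
}

#' Exclude artifact-contaminated subimages
#'
#' Subimages overlapping the annotation mask (scratches, hemorrhagic
#' necrosis) by more than 10 percent of their area are flagged excluded
#' and dropped.
#'
#' @param subimages list of `sub_image` tiled from one source image.
#' @param exclusion_mask logical matrix aligned with the source image.
#' @param max_overlap overlap fraction threshold; default 0.1.
#' @return The retained subimages.
#' @export
exclude_artifacts <- function(subimages, exclusion_mask, max_overlap = 0.1) {
  keep <- vapply(subimages, function(s) {
    size <- nrow(s$patch)
    r <- s$origin["row"] + seq_len(size)
    cc <- s$origin["col"] + seq_len(size)
    if (max(r) > nrow(exclusion_mask) || max(cc) > ncol(exclusion_mask))
      stopf("exclusion mask smaller than the tiled image")
    mean(exclusion_mask[r, cc]) <= max_overlap
  }, logical(1))
  subimages[keep]
}

#' Stratified train/test split
#'
#' Seeded shuffle stratified by label; `round(train_fraction * n)` per
#' class goes to training. Train and test are disjoint and exhaustive.
#'
#' @param labels vector of class labels.
#' @param train_fraction default 0.6 (the 6:4 design ratio).
#' @param seed RNG seed.
#' @return List of index vectors `train`, `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.6, seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2L) stopf("need at least 2 classes to stratify")
  if (length(labels) < 2L || any(tab < 2L))
    stopf("each class needs at least 2 members")
  with_seed(seed, {
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# ---- logistic margin model --------------------------------------------

#' Train the logistic margin model
#'
#' Features are standardized with training mean/sd; the logistic
#' regression is fit by iteratively reweighted least squares with an L2
#' ridge of 1e-6 as a numerical guard, converged when the log-likelihood
#' changes by less than 1e-8. The operating threshold is set by Youden's
#' J on the training ROC.
#'
#' @param features n x p numeric matrix or data frame.
#' @param labels vector with exactly two classes; "positive"/1/TRUE is
#'   the event.
#' @param ridge L2 penalty; default 1e-6.
#' @param max_iter IRLS iteration cap.
#' @return A `margin_model`: `coefficients` (intercept + per feature,
#'   standardized scale), `center`, `scale`, `threshold`, `se`
#'   (Wald standard errors), `converged`, `log_likelihood`.
#' @export
train_margin_model <- function(features, labels, ridge = 1e-6,
                               max_iter = 100L) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stopf("non-finite feature values")
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, center), 2, scale_, "/"))
  p <- ncol(Xs)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xs %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xs, Xs * w) + diag(ridge, p)
    g <- crossprod(Xs, y - mu) - ridge * beta
    beta <- beta + drop(solve(H, g))
    eta <- drop(Xs %*% beta)
    ll <- sum(y * eta - log1p(exp(eta))) - ridge / 2 * sum(beta^2)
    if (abs(ll - ll_old) < 1e-8) { converged <- TRUE; break }
    ll_old <- ll
  }
  eta <- drop(Xs %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  se <- sqrt(diag(solve(crossprod(Xs, Xs * w) + diag(ridge, p))))
  scores <- mu
  roc_tr <- roc_curve(scores, y)
  youden <- roc_tr$tpr - roc_tr$fpr
  k <- which.max(youden)
  # any threshold in the interval down to the next observed score yields
  # the same training confusion; the midpoint generalizes best
  threshold <- if (k < length(roc_tr$thresholds))
    (min(roc_tr$thresholds[k], 1) + roc_tr$thresholds[k + 1L]) / 2
  else roc_tr$thresholds[k]
  structure(list(coefficients = setNames(beta, c("(Intercept)",
                                                 colnames(X) %||%
                                                   paste0("f", seq_len(p - 1L)))),
                 se = se, center = center, scale = scale_,
                 threshold = threshold, converged = converged,
                 log_likelihood = ll, n = nrow(X)),
            class = "margin_model")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) return(as.integer(labels != 0))
  lv <- as.character(labels)
  as.integer(lv %in% c("positive", "pos", "1", "TRUE", "tumor"))
}

#' @export
predict.margin_model <- function(object, newdata, type = c("prob", "class"),
                                 ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xs <- cbind(1, sweep(sweep(X, 2, object$center), 2, object$scale, "/"))
  p <- drop(1 / (1 + exp(-Xs %*% object$coefficients)))
  if (type == "prob") p else as.integer(p >= object$threshold)
}

#' @export
print.margin_model <- function(x, ...) {
  cat(sprintf("margin_model: %d features, threshold %.3f, %sconverged\n",
              length(x$coefficients) - 1L, x$threshold,
              if (x$converged) "" else "NOT "))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' ROC curve over all score thresholds
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (see [train_margin_model]).
#' @return List: `thresholds`, `tpr`, `fpr` (monotone nondecreasing),
#'   `auc` (trapezoid).
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stopf("both classes required for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # collapse tied scores to one operating point
  last_tie <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- tp[last_tie]; fp <- fp[last_tie]; th <- ss[last_tie]
  tpr <- c(0, tp / sum(y)); fpr <- c(0, fp / sum(1 - y))
  th <- c(Inf, th)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc)
}

#' Wilson 95 percent confidence interval for a proportion
#'
#' @param k successes, `n` trials.
#' @param n trials.
#' @param conf confidence level; default 0.95.
#' @return Length-2 numeric (lower, upper).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = mid - hw, upper = mid + hw)
}

#' Evaluate the margin model on a test set
#'
#' ROC over all thresholds with trapezoid AUC; sensitivity and
#' specificity at the model's operating threshold with Wilson 95 percent
#' confidence intervals; confusion counts; and single-feature ROCs
#' (each feature oriented so its AUC is at least 0.5).
#'
#' @param model a `margin_model`.
#' @param features n x p test feature matrix.
#' @param labels test labels (both classes present).
#' @return An `eval_report` list.
#' @export
evaluate_margin_model <- function(model, features, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stopf("both classes required in the test set")
  scores <- predict(model, features)
  roc <- roc_curve(scores, y)
  pred <- as.integer(scores >= model$threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  X <- as.matrix(features)
  per_feature <- lapply(seq_len(ncol(X)), function(j) {
    a <- roc_curve(X[, j], y)$auc
    list(feature = colnames(X)[j] %||% paste0("f", j),
         auc = max(a, 1 - a), flipped = a < 0.5)
  })
  structure(list(roc = roc, auc = roc$auc,
                 sensitivity = tp / (tp + fn),
                 sensitivity_ci = wilson_ci(tp, tp + fn),
                 specificity = tn / (tn + fp),
                 specificity_ci = wilson_ci(tn, tn + fp),
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 threshold = model$threshold,
                 per_feature = per_feature),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUC %.3f | sens %.1f%% (%.1f-%.1f) | spec %.1f%% (%.1f-%.1f)\n",
              x$auc, 100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2], 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  invisible(x)
}

#' Positive-margin areas from a subimage call map
#'
#' 8-connected components of positive subimage calls; each component's
#' area is its subimage count times the squared subimage edge. A single
#' positive 128-pixel subimage at 5x covers 0.1152^2 = 0.0133 mm^2.
#'
#' @param positive_map logical matrix over the subimage grid.
#' @param edge_mm subimage edge length, mm; default `128 * 4.5 / 5 / 1000`.
#' @return Numeric vector of component areas, mm^2 (empty when no
#'   positives).
#' @export
margin_areas <- function(positive_map, edge_mm = 128 * 4.5 / 5 / 1000) {
  if (!any(positive_map)) return(numeric(0))
  lab <- label_components(positive_map)
  as.numeric(tabulate(lab[lab > 0L], max(lab))) * edge_mm^2
}

#' Feature table I/O
#'
#' One row per subimage: id, the four features, label, excluded flag and
#' section distance.
#'
#' @param subimages list of `sub_image`.
#' @param features list or matrix of feature vectors aligned with
#'   `subimages`.
#' @param path CSV path.
#' @return `path` invisibly, or a data frame.
#' @export
write_feature_table <- function(subimages, features, path) {
  fm <- do.call(rbind, lapply(features, as.numeric))
  colnames(fm) <- c("nc_ratio", "avg_nuclear_intensity",
                    "mean_nuclear_area", "std_nuclear_area")
  df <- data.frame(id = seq_along(subimages), fm,
                   label = vapply(subimages, `[[`, "", "label"),
                   excluded = vapply(features, function(f)
                     isTRUE(attr(f, "excluded")), logical(1)),
                   section_distance = vapply(subimages, `[[`, numeric(1),
                                             "section_distance"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) read.csv(path)
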