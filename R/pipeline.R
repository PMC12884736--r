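# End-to-end synthetic demo pipeline and run configuration.

#' Run configuration
#'
#' Aggregates the standard constants: objective preset (du = 4.5 um,
#' pixel_N = 5120), 0.8 overlap factor, 0.2 mm elevation padding,
#' 128-pixel subimages and the 6:4 train/test split.
#'
#' @param objective preset name ("5x", "10x", "20x").
#' @param shape synthetic surface shape for the demo run.
#' @param extent,amplitude surface extent and bump amplitude, mm.
#' @param mesh_n surface vertex resolution.
#' @param tile_px simulated tile side, pixels (a native-resolution
#'   central crop of the FOV).
#' @param subimage_px subimage side for feature extraction.
#' @param overlap_factor grid spacing fraction of the FOV edge.
#' @param pad elevation padding, mm.
#' @param train_fraction train split fraction.
#' @param lambda view-selection smoothness weight.
#' @param seed master RNG seed.
#' @param out output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(objective = "5x", shape = "bumpy", extent = 15,
                       amplitude = 1.5, mesh_n = 40L, tile_px = 256L,
                       subimage_px = 128L, overlap_factor = 0.8, pad = 0.2,
                       train_fraction = 0.6, lambda = 0.5, seed = 1L,
                       out = tempfile("musescan_run_")) {
  cfg <- list(objective = objective, shape = shape, extent = extent,
              amplitude = amplitude, mesh_n = as.integer(mesh_n),
              tile_px = as.integer(tile_px),
              subimage_px = as.integer(subimage_px),
              overlap_factor = overlap_factor, pad = pad,
              train_fraction = train_fraction, lambda = lambda,
              seed = as.integer(seed), out = out)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  obj <- objective_preset(cfg$objective)
  # the presets must reproduce the instrument FOV arithmetic
  stopifnot(abs(compute_fov(obj) - 4.5 * 5120 / obj$magnification / 1000) < 1e-12)
  if (cfg$overlap_factor <= 0 || cfg$overlap_factor > 1)
    stopf("overlap_factor must be in (0, 1]")
  if (cfg$tile_px < cfg$subimage_px)
    stopf("tile_px must be >= subimage_px")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [run_config].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s (%s)", stage, sprintf(fmt, ...),
                  format(Sys.time(), "%H:%M:%S")))
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates a synthetic tissue surface, plans the scan trajectory,
#' simulates per-grid focal stacks of class-labeled tissue textures,
#' fuses them to extended-depth-of-field tiles, synthesizes the textured
#' surface, extracts nuclear features from 128-pixel subimages, trains
#' the logistic margin model on a 6:4 split and evaluates it. Writes the
#' trajectory JSON, fused tiles (16-bit TIFF), textured OBJ/MTL/PNG,
#' feature CSV, model JSON, ROC CSV and evaluation JSON into
#' `config$out`.
#'
#' @param config a `run_config`.
#' @return List: `dir`, `artifacts` (named paths), `evaluation`
#'   (an `eval_report`), `trajectory`, `n_subimages`.
#' @export
run_pipeline <- function(config = run_config()) {
  config <- validate_run_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$out, "tiles"), showWarnings = FALSE)
  obj <- objective_preset(config$objective)
  A <- intrinsic_matrix(obj$magnification)
  fov <- compute_fov(obj, A)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # -- plan ------------------------------------------------------------
  traj <- run_stage("plan", {
    stage_msg("plan", "surface '%s', FOV %.3f mm", config$shape, fov)
    mesh <- if (config$shape == "plane")
      make_surface("plane", extent = config$extent, n = config$mesh_n)
    else make_surface(config$shape, extent = config$extent,
                      amplitude = config$amplitude, n = config$mesh_n,
                      seed = config$seed)
    plan_trajectory(mesh, obj, fov, config$overlap_factor, config$pad)
  })
  mesh <- NULL # mesh lives in the closure above; recover from grids
  grids <- attr(traj, "grids")
  traj_path <- file.path(config$out, "trajectory.json")
  write_trajectory(traj, traj_path)
  stage_msg("plan", "%d grids, rotation cost %.2f", length(grids),
            traj$total_cost)

  # -- acquire + fuse --------------------------------------------------
  H <- compose_homography(A, extrinsic_pose(), estimated = TRUE)
  pitch_um <- A$du / A$m
  crop_mm <- config$tile_px * pitch_um / 1000
  fused <- vector("list", length(grids))
  classes <- character(length(grids))
  poses <- vector("list", length(grids))
  run_stage("fuse", {
    for (i in seq_along(grids)) {
      g <- grids[[i]]
      classes[i] <- if (i %% 2L == 1L) "positive" else "negative"
      params <- tissue_params(classes[i])
      tex <- make_tissue_texture(params, extent_mm = crop_mm,
                                 pixel_pitch_um = pitch_um,
                                 seed = config$seed * 10000L + i)
      cx <- g$center$position
      pattern <- function(x, y) {
        px <- clamp((x - cx[1]) / (pitch_um / 1000) + config$tile_px / 2,
                    0, config$tile_px - 1)
        py <- clamp((y - cx[2]) / (pitch_um / 1000) + config$tile_px / 2,
                    0, config$tile_px - 1)
        bilinear_sample(tex$image, cbind(px, py))
      }
      pose <- grid_pose(g, obj)
      poses[[i]] <- pose
      sched <- elevation_schedule(g, obj, config$pad)
      focus <- sum(cx * g$avg_normal)
      sharp <- render_tile(pattern, pose, H, cx,
                           tile_px = config$tile_px,
                           pixel_N = config$tile_px)
      stack <- make_focal_stack(sharp, sched,
                                defocus_model(focus, blur_scale = 20),
                                grid_id = g$id)
      tile <- fuse_stack(stack)
      tile$image <- equalize_tile(tile$image)
      fused[[i]] <- tile
      tiff::writeTIFF(clamp(tile$image / 255, 0, 1),
                      file.path(config$out, "tiles",
                                sprintf("tile_%03d.tif", g$id)),
                      bits.per.sample = 16L)
    }
    stage_msg("fuse", "%d tiles fused", length(grids))
  })

  # -- synthesize ------------------------------------------------------
  obj_path <- run_stage("synthesize", {
    mesh2 <- make_surface(config$shape, extent = config$extent,
                          amplitude = config$amplitude, n = config$mesh_n,
                          seed = config$seed)
    projs <- lapply(seq_along(grids), function(i)
      project_tile(fused[[i]], poses[[i]], H, mesh2,
                   center = grids[[i]]$center$position,
                   pixel_N = config$tile_px))
    cands <- lapply(seq_len(nrow(mesh2$faces)), function(fi) {
      hits <- which(vapply(projs, function(p) p$assigned[fi], logical(1)))
      lapply(hits, function(ti)
        list(tile_id = ti, view_axis = projs[[ti]]$view_axis))
    })
    sel <- select_views(mesh2, cands, lambda = config$lambda)
    ts <- texture_surface(mesh2, fused, projs, sel$labels)
    p <- write_textured_surface(ts, file.path(config$out, "textured"))
    stage_msg("synthesize", "%d facets textured",
              sum(!is.na(sel$labels)))
    p
  })

  # -- features --------------------------------------------------------
  feat <- run_stage("features", {
    subs <- list(); feats <- list()
    for (i in seq_along(grids)) {
      tiles <- tile_image(fused[[i]]$image, size = config$subimage_px,
                          pixel_mm = pitch_um / 1000,
                          label = classes[i])
      for (s in tiles) {
        seg <- segment_nuclei(s)
        fv <- extract_features(s, seg)
        if (isTRUE(attr(fv, "excluded"))) next
        s$section_distance <- 0
        subs[[length(subs) + 1L]] <- s
        feats[[length(feats) + 1L]] <- fv
      }
    }
    path <- file.path(config$out, "features.csv")
    write_feature_table(subs, feats, path)
    stage_msg("features", "%d subimages", length(subs))
    list(subs = subs, X = do.call(rbind, feats),
         labels = vapply(subs, `[[`, "", "label"), path = path)
  })

  # -- train + evaluate ------------------------------------------------
  run_stage("evaluate", {
    colnames(feat$X) <- c("nc_ratio", "avg_nuclear_intensity",
                          "mean_nuclear_area", "std_nuclear_area")
    idx <- split_dataset(feat$labels, config$train_fraction,
                         seed = config$seed)
    model <- train_margin_model(feat$X[idx$train, , drop = FALSE],
                                feat$labels[idx$train])
    report <- evaluate_margin_model(model,
                                    feat$X[idx$test, , drop = FALSE],
                                    feat$labels[idx$test])
    model_path <- file.path(config$out, "model.json")
    jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                              center = model$center, scale = model$scale,
                              threshold = model$threshold,
                              converged = model$converged),
                         model_path, auto_unbox = TRUE, digits = NA)
    roc_path <- file.path(config$out, "roc.csv")
    write.csv(data.frame(threshold = report$roc$thresholds,
                         fpr = report$roc$fpr, tpr = report$roc$tpr),
              roc_path, row.names = FALSE)
    eval_path <- file.path(config$out, "evaluation.json")
    jsonlite::write_json(list(auc = report$auc,
                              sensitivity = report$sensitivity,
                              sensitivity_ci = report$sensitivity_ci,
                              specificity = report$specificity,
                              specificity_ci = report$specificity_ci,
                              confusion = as.list(report$confusion),
                              per_feature = report$per_feature,
                              n_train = length(idx$train),
                              n_test = length(idx$test)),
                         eval_path, auto_unbox = TRUE, digits = NA)
    stage_msg("evaluate", "AUC %.3f, sens %.1f%%, spec %.1f%%",
              report$auc, 100 * report$sensitivity,
              100 * report$specificity)
    list(dir = config$out,
         artifacts = c(trajectory = traj_path,
                       tiles = file.path(config$out, "tiles"),
                       textured_obj = obj_path,
                       features = feat$path,
                       model = model_path,
                       roc = roc_path,
                       evaluation = eval_path),
         evaluation = report, trajectory = traj,
         n_subimages = length(feat$subs))
  })
}
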