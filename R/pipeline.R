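#' End-to-end pipeline configuration
#'
#' Validated nested configuration for [run_pipeline()]: simulate ->
#' residualize -> train -> relevance -> occlude -> evaluate. One global seed
#' fans out to fixed per-stage seeds (seed * 100 + stage index) so each
#' stage is individually reproducible. In `mode = "raw"` the residualization
#' stage is skipped and training uses the raw-input epoch default (twice the
#' residualized epochs, reflecting slower convergence on uncorrected
#' intensities).
#'
#' @param out output directory.
#' @param mode `"residualized"` (default) or `"raw"`.
#' @param cohort a [cohort_spec()] (the seed inside it is overridden by the
#'   pipeline seed).
#' @param train a [train_config()]; epochs are doubled in raw mode.
#' @param folds number of cross-validation folds, or 1 for a single
#'   stratified 80/20-style split (fold 1 as test).
#' @param occlusion list with `enabled`, `cube_edge`, `attenuation`,
#'   `stride`.
#' @param seed global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out = tempfile("relmap3d_run_"),
                       mode = c("residualized", "raw"),
                       cohort = cohort_spec(),
                       train = demo_train_config(),
                       folds = 5L,
                       occlusion = list(enabled = FALSE, cube_edge = 10L,
                                        attenuation = 0.5, stride = 6L),
                       seed = 1L) {
  mode <- match.arg(mode)
  known <- c("enabled", "cube_edge", "attenuation", "stride")
  unknown <- setdiff(names(occlusion), known)
  if (length(unknown))
    stop("unknown occlusion option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(out = out, mode = mode, cohort = cohort, train = train,
                 folds = as.integer(folds),
                 occlusion = utils::modifyList(
                   list(enabled = FALSE, cube_edge = 10L, attenuation = 0.5,
                        stride = 6L), occlusion),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Strict: unknown keys anywhere in the document are errors.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("out", "mode", "cohort", "train", "folds", "occlusion", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  co <- if (!is.null(cfg$cohort)) do.call(cohort_spec, cfg$cohort) else cohort_spec()
  tr <- if (!is.null(cfg$train)) do.call(train_config, cfg$train) else demo_train_config()
  run_config(out = cfg$out %||% tempfile("relmap3d_run_"),
             mode = cfg$mode %||% "residualized", cohort = co, train = tr,
             folds = cfg$folds %||% 5L,
             occlusion = as.list(cfg$occlusion %||% list(enabled = FALSE)),
             seed = cfg$seed %||% 1L)
}

stage_seed <- function(config, stage) config$seed * 100L + stage

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, residualizes it on the controls (unless in raw mode),
#' trains the CNN on one stratified split, computes relevance maps and the
#' hippocampus relevance/volume correlation, optionally runs an occlusion
#' scan, evaluates the CNN against the hippocampus-volume baseline on the
#' shared test split, and writes a manifest (seeds, versions, artifact
#' hashes, per-stage wall time) plus a metrics JSON into the output
#' directory. Reruns with the same configuration reproduce the metrics
#' exactly.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return the run manifest (invisibly returns its list form).
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  # simulate
  say("stage 1/6: simulate cohort")
  spec <- config$cohort
  spec$seed <- stage_seed(config, 1L)
  cohort <- simulate_cohort(spec)
  write_covariates(cohort$records, file.path(config$out, "covariates.tsv"))
  write_atlas(cohort$atlas, file.path(config$out, "atlas.nii.gz"))
  tick("simulate")

  # residualize
  resid_model <- NULL
  if (config$mode == "residualized") {
    say("stage 2/6: residualize on controls")
    ctrl <- cohort$records$diagnosis == "CN"
    resid_model <- fit_residualizer(cohort$volumes[ctrl],
                                    cohort$records[ctrl, , drop = FALSE])
    inputs <- apply_residualizer(cohort$volumes, cohort$records, resid_model)
    write_residual_model(resid_model,
                         file.path(config$out, "residual_model.nii.gz"))
  } else {
    say("stage 2/6: raw mode, residualization skipped")
    inputs <- cohort$volumes
  }
  tick("residualize")

  # train
  epochs <- if (config$mode == "raw") config$train$epochs * 2L else config$train$epochs
  tcfg <- config$train
  tcfg$epochs <- as.integer(epochs)
  tcfg$seed <- stage_seed(config, 3L)
  dataset <- list(volumes = inputs, records = cohort$records)
  say("stage 3/6: train (%d epoch(s), %s mode)", epochs, config$mode)
  folds <- stratified_folds(cohort$records, k = max(config$folds, 2L),
                            seed = tcfg$seed)
  test_idx <- folds == 1L
  train_set <- list(volumes = dataset$volumes[!test_idx],
                    records = dataset$records[!test_idx, , drop = FALSE])
  test_set <- list(volumes = dataset$volumes[test_idx],
                   records = dataset$records[test_idx, , drop = FALSE])
  model <- train_fold(train_set, test_set, config = tcfg, fold_id = 1L)
  tick("train")

  # relevance
  say("stage 4/6: relevance maps + correlation")
  rep_ <- relevance_volume_report(model, inputs, cohort$records, cohort$atlas,
                                  density_volumes = cohort$volumes)
  write.table(rep_$table, file.path(config$out, "relevance_correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # group-mean relevance maps (viewer analogue)
  y <- binary_labels(cohort$records$diagnosis)
  for (grp in c(0L, 1L)) {
    idx <- which(y == grp)
    acc <- array(0, spec$grid_shape)
    for (j in idx)
      acc <- acc + relevance_map(model, inputs[[j]])$values
    mv <- gm_volume(acc / length(idx), voxel_size_mm = spec$voxel_size_mm,
                    space_tag = "relevance")
    write_volume(mv, file.path(config$out,
                               sprintf("mean_relevance_%s.nii.gz",
                                       c("CN", "disease")[grp + 1L])))
  }
  tick("relevance")

  # occlusion (optional)
  occ_summary <- NULL
  if (isTRUE(config$occlusion$enabled)) {
    say("stage 5/6: occlusion scan")
    j <- which(y == 0L)[1]
    # atrophy is simulated on the raw density map; in residualized mode the
    # model still sees residual images, so residualization is re-applied to
    # every occluded volume
    prep <- if (config$mode == "residualized") {
      pred_j <- array(predict(resid_model,
                              cohort$records[j, , drop = FALSE])[1, ],
                      spec$grid_shape)
      function(v) v - pred_j
    }
    occ <- occlusion_scan(model, cohort$volumes[[j]],
                          cube_edge = config$occlusion$cube_edge,
                          attenuation = config$occlusion$attenuation,
                          stride = config$occlusion$stride,
                          preprocess = prep)
    occ_summary <- list(cube_edge_mm = occ$cube_edge_mm,
                        baseline_prob = occ$baseline$prob,
                        max_prob = max(occ$probability_grid))
  } else say("stage 5/6: occlusion scan disabled")
  tick("occlude")

  # evaluate
  say("stage 6/6: evaluate")
  cw <- compute_class_weights(table(binary_labels(train_set$records$diagnosis)))
  ev <- evaluate_on(model, test_set, cw)
  cnn_auc <- roc_auc(ev$scores, ev$labels)
  hip_res <- rep_$hippocampus_volume_ml
  base <- volumetric_baseline(hip_res[!test_idx], y[!test_idx],
                              hip_res[test_idx], y[test_idx])
  metrics <- list(
    mode = config$mode, seed = config$seed,
    n_subjects = length(inputs), n_test = sum(test_idx),
    selected_epoch = model$selected_epoch,
    cnn = list(test_balanced_accuracy = ev$bacc, test_auc = cnn_auc),
    volumetric_baseline = list(test_balanced_accuracy = base$balanced_accuracy,
                               test_auc = base$auc,
                               volume_threshold_ml = base$volume_threshold_ml),
    hippocampus_relevance_volume_r =
      rep_$table$median_r[rep_$table$region == "hippocampus"],
    occlusion = occ_summary)
  jsonlite::write_json(metrics, file.path(config$out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  tick("evaluate")

  artifacts <- list.files(config$out, full.names = TRUE)
  artifacts <- setdiff(artifacts, file.path(config$out, "manifest.json"))
  manifest <- list(
    package_version = as.character(packageVersion("relmap3d")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    stage_seeds = list(simulate = stage_seed(config, 1L),
                       train = stage_seed(config, 3L)),
    mode = config$mode,
    timings_sec = as.list(timings),
    artifact_md5 = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, metrics = metrics, model = model,
                 out = config$out))
}

#' Summarize a completed pipeline run
#'
#' Renders a plain-text report from the artifacts in a run directory:
#' configuration echo, test metrics for the CNN and the hippocampus-volume
#' baseline, the relevance/volume correlation table, and mid-slice renders
#' of the group-mean relevance maps (PNG). A missing relevance stage yields
#' a partial report with a warning.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param render_png also write slice renders of the mean relevance maps.
#' @return path of the report file, invisibly.
#' @export
make_report <- function(run_dir, render_png = TRUE) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json in ", run_dir, " - incomplete run", call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  metrics <- jsonlite::read_json(file.path(run_dir, "metrics.json"),
                                 simplifyVector = TRUE)
  lines <- c(
    "relmap3d pipeline report",
    "========================",
    sprintf("created: %s   package %s   seed %d   mode %s",
            manifest$created, manifest$package_version, manifest$seed,
            manifest$mode),
    "",
    sprintf("subjects: %d (test %d), selected epoch %s",
            metrics$n_subjects, metrics$n_test, metrics$selected_epoch),
    sprintf("CNN:       balanced accuracy %.3f, AUC %.3f",
            metrics$cnn$test_balanced_accuracy, metrics$cnn$test_auc),
    sprintf("baseline:  balanced accuracy %.3f, AUC %.3f (volume threshold %+.2f ml)",
            metrics$volumetric_baseline$test_balanced_accuracy,
            metrics$volumetric_baseline$test_auc,
            metrics$volumetric_baseline$volume_threshold_ml),
    sprintf("hippocampus relevance vs volume: r = %.3f",
            metrics$hippocampus_relevance_volume_r),
    "")
  cor_path <- file.path(run_dir, "relevance_correlations.tsv")
  if (file.exists(cor_path)) {
    tab <- read.delim(cor_path)
    lines <- c(lines, "relevance/volume correlations by region:",
               utils::capture.output(print(tab)), "")
  } else {
    warning("relevance stage artifacts missing; partial report", call. = FALSE)
    lines <- c(lines, "[relevance stage missing]", "")
  }
  if (render_png) {
    for (grp in c("CN", "disease")) {
      f <- file.path(run_dir, sprintf("mean_relevance_%s.nii.gz", grp))
      if (file.exists(f)) {
        v <- read_volume(f)
        png_path <- file.path(run_dir, sprintf("mean_relevance_%s.png", grp))
        grDevices::png(png_path, width = 480, height = 480)
        graphics::image(v[, , (dim(v)[3] + 1) %/% 2], useRaster = TRUE,
                        main = sprintf("mean relevance (%s), mid-axial slice", grp))
        grDevices::dev.off()
        lines <- c(lines, sprintf("render: %s", basename(png_path)))
      }
    }
  }
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
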