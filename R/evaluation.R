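#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, counting ties as 1/2 (computed via midranks).
#'
#' @param scores numeric risk scores (higher = more disease-like).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Youden-index threshold selection
#'
#' Scans the midpoints between adjacent sorted unique scores, classifies
#' positive at `score >= threshold`, and returns the threshold maximizing
#' the Youden index `J = sensitivity + specificity - 1` (equivalently the
#' balanced accuracy). Ties resolve to the lowest qualifying threshold.
#'
#' @inheritParams roc_auc
#' @return An `roc_result` list: `auc`, `threshold`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `youden_j`, `n_pos`, `n_neg`.
#' @examples
#' youden_threshold(c(0.1, 0.35, 0.4, 0.8), c(0, 1, 0, 1))$threshold  # 0.225
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  cand <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else u
  best <- list(j = -Inf, thr = NA_real_, sens = NA_real_, spec = NA_real_)
  for (thr in cand) {
    pred <- as.integer(scores >= thr)
    sens <- sum(pred == 1L & labels == 1L) / npos
    spec <- sum(pred == 0L & labels == 0L) / nneg
    j <- sens + spec - 1
    if (j > best$j) best <- list(j = j, thr = thr, sens = sens, spec = spec)
  }
  structure(list(auc = roc_auc(scores, labels), threshold = best$thr,
                 sensitivity = best$sens, specificity = best$spec,
                 balanced_accuracy = (best$sens + best$spec) / 2,
                 youden_j = best$j, n_pos = npos, n_neg = nneg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f, threshold %.4g -> sens %.3f, spec %.3f, bal.acc %.3f (n+ %d, n- %d)\n",
              x$auc, x$threshold, x$sensitivity, x$specificity,
              x$balanced_accuracy, x$n_pos, x$n_neg))
  invisible(x)
}

#' Balanced accuracy of binary predictions
#'
#' Mean of sensitivity and specificity; robust to class imbalance.
#'
#' @param predictions binary predictions (0/1).
#' @param labels binary labels (0/1).
#' @return scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(predictions, labels) {
  predictions <- as.integer(as.logical(predictions))
  labels <- as.integer(as.logical(labels))
  stopifnot(length(predictions) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the labels", call. = FALSE)
  sens <- sum(predictions == 1L & labels == 1L) / sum(labels == 1L)
  spec <- sum(predictions == 0L & labels == 0L) / sum(labels == 0L)
  (sens + spec) / 2
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3), both non-constant.
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  cor(x, y, method = "pearson")
}

#' Hippocampus-volume baseline classifier
#'
#' Residual hippocampus volumes (covariate-corrected; lower volume = higher
#' disease risk) are turned into risk scores by sign flip, the Youden
#' threshold is derived on the training residuals, and sensitivity,
#' specificity, balanced accuracy and AUC are reported on the test
#' residuals. The volume threshold is the negated score threshold, i.e.
#' subjects whose residual volume falls below it are classified as disease.
#'
#' @param train_residuals_ml,test_residuals_ml residualized volumes (ml) from
#'   [residualize_scalar()].
#' @param train_labels,test_labels binary labels (0 = control, 1 = disease).
#' @return An `roc_result` for the test set with the extra fields
#'   `volume_threshold_ml` (train-derived) and `train` (the training
#'   `roc_result`).
#' @export
volumetric_baseline <- function(train_residuals_ml, train_labels,
                                test_residuals_ml, test_labels) {
  tr <- youden_threshold(-train_residuals_ml, train_labels)
  sc <- -test_residuals_ml
  lab <- as.integer(as.logical(test_labels))
  pred <- as.integer(sc >= tr$threshold)
  sens <- sum(pred == 1L & lab == 1L) / sum(lab == 1L)
  spec <- sum(pred == 0L & lab == 0L) / sum(lab == 0L)
  out <- structure(list(auc = roc_auc(sc, lab), threshold = tr$threshold,
                        sensitivity = sens, specificity = spec,
                        balanced_accuracy = (sens + spec) / 2,
                        youden_j = sens + spec - 1,
                        n_pos = sum(lab == 1L), n_neg = sum(lab == 0L)),
                   class = "roc_result")
  out$volume_threshold_ml <- -tr$threshold
  out$train <- tr
  out
}

#' Region relevance vs. hippocampus volume correlation table
#'
#' For each trained model and each atlas region (plus the whole brain), the
#' per-subject region relevance sum is correlated (Pearson) with the
#' residualized hippocampus volume. With a model that has learnt hippocampal
#' atrophy, hippocampus relevance rises as hippocampus volume falls, so the
#' correlation is strongly negative.
#'
#' @param models list of trained `cnn3d` (or a single model).
#' @param volumes list of input volumes (as fed to the models, i.e. residual
#'   images in residualized mode).
#' @param records data.frame with the covariate columns and `diagnosis`.
#' @param atlas a `region_atlas` with a `"hippocampus"` region.
#' @param density_volumes volumes used for volumetry (unresidualized density
#'   maps); defaults to `volumes`.
#' @param target_class class whose relevance is mapped (default disease).
#' @return list with `table` (data.frame: region x model correlations and
#'   the across-model median), `hippocampus_volume_ml` (residualized) and
#'   `relevance` (subjects x regions x models array of relevance sums).
#' @export
relevance_volume_report <- function(models, volumes, records, atlas,
                                    density_volumes = NULL,
                                    target_class = NULL) {
  if (inherits(models, "cnn3d")) models <- list(models)
  density_volumes <- density_volumes %||% volumes
  hip_mask <- atlas_region_mask(atlas, "hippocampus")
  hv <- vapply(density_volumes, region_volume_ml, numeric(1), mask = hip_mask)
  rs <- residualize_scalar(hv, records, records$diagnosis == "CN")
  regions <- c(unname(atlas$region_names), "whole_brain")
  masks <- c(lapply(unname(atlas$region_names),
                    function(r) atlas_region_mask(atlas, r)),
             list(array(TRUE, dim(atlas$labels))))
  n <- length(volumes)
  rel <- array(NA_real_, c(n, length(regions), length(models)),
               dimnames = list(NULL, regions, NULL))
  for (m in seq_along(models)) {
    for (j in seq_len(n)) {
      map <- relevance_map(models[[m]], volumes[[j]], target_class = target_class)
      for (g in seq_along(masks))
        rel[j, g, m] <- region_relevance_sum(map, masks[[g]])
    }
  }
  cors <- sapply(seq_along(models), function(m)
    vapply(seq_along(regions), function(g)
      pearson_r(rel[, g, m], rs$residuals), numeric(1)))
  cors <- matrix(cors, nrow = length(regions),
                 dimnames = list(regions, paste0("model", seq_along(models))))
  tab <- data.frame(region = regions, cors,
                    median_r = apply(cors, 1, stats::median),
                    row.names = NULL, check.names = FALSE)
  list(table = tab, hippocampus_volume_ml = rs$residuals, relevance = rel)
}
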