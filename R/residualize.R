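#' Fit the covariate residualization model on healthy controls
#'
#' For every feature (voxel, or scalar measure) an ordinary least squares
#' model `feature ~ age + sex + tiv + field_strength` is fitted on control
#' subjects only. The fitted predictions are later subtracted from all
#' subjects' features ("fit on controls, apply to all"), removing normal-aging
#' and head-size variance from the disease signal.
#'
#' Coefficients are obtained through a pseudo-inverse of the design matrix
#' (relative singular-value tolerance 1e-10), so zero-variance features are
#' handled gracefully: their slopes are zero and the intercept equals the
#' feature mean. A rank-deficient design (e.g. a constant covariate) is an
#' error naming the offending column.
#'
#' @param control_features numeric matrix `n_controls x n_features`, a list
#'   of 3D volumes, or a 4D array (subjects last).
#' @param control_covariates data.frame with `age`, `sex`, `tiv`,
#'   `field_strength` for the same subjects, in order.
#' @return A `residual_model`: coefficients (5 x n_features: intercept, age,
#'   sex, tiv, field_strength), `feature_shape`, `fit_n`.
#' @examples
#' cov <- data.frame(age = c(60, 65, 70, 75, 80, 85), sex = c(0, 1, 0, 1, 0, 1),
#'                   tiv = 1400 + 1:6 * 10, field_strength = c(0, 1, 1, 0, 1, 0))
#' y <- 1 - 0.005 * cov$age
#' m <- fit_residualizer(matrix(y, ncol = 1), cov)
#' coef(m)
#' @export
fit_residualizer <- function(control_features, control_covariates) {
  Y <- as_feature_matrix(control_features)
  X <- design_matrix(control_covariates, nrow(Y))
  if (nrow(Y) < 6)
    stop("need at least 6 control subjects to fit the residualizer",
         call. = FALSE)
  check_design_rank(X)
  B <- pinv(X, rtol = 1e-10) %*% Y
  structure(list(coefficients = B,
                 feature_shape = attr(Y, "grid_dim") %||% ncol(Y),
                 fit_n = nrow(Y),
                 covariates = c("intercept", "age", "sex", "tiv", "field_strength")),
            class = "residual_model")
}

as_feature_matrix <- function(features) {
  if (is.list(features) || (!is.null(dim(features)) && length(dim(features)) == 4L))
    return(stack_volumes(features))
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  storage.mode(features) <- "double"
  features
}

design_matrix <- function(covariates, n) {
  need <- c("age", "sex", "tiv", "field_strength")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(covariates) != n)
    stop(sprintf("covariate rows (%d) do not match feature rows (%d)",
                 nrow(covariates), n), call. = FALSE)
  cbind(intercept = 1,
        age = covariates$age, sex = covariates$sex,
        tiv = covariates$tiv, field_strength = covariates$field_strength)
}

check_design_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    sds <- apply(X[, -1, drop = FALSE], 2, sd)
    bad <- names(sds)[sds == 0]
    hint <- if (length(bad)) paste0(" (constant column: ",
                                    paste(bad, collapse = ", "), ")") else ""
    stop("covariate design matrix is rank deficient", hint, call. = FALSE)
  }
  invisible(TRUE)
}

pinv <- function(X, rtol = 1e-10) {
  s <- svd(X)
  keep <- s$d > rtol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' @export
print.residual_model <- function(x, ...) {
  nf <- ncol(x$coefficients)
  cat(sprintf("residual_model: %d feature(s), fitted on %d controls\n",
              nf, x$fit_n))
  if (nf == 1)
    print(stats::setNames(drop(x$coefficients), x$covariates))
  invisible(x)
}

#' @export
coef.residual_model <- function(object, ...) {
  b <- object$coefficients
  rownames(b) <- object$covariates
  if (ncol(b) == 1) drop(b) else b
}

#' Predicted features under the covariate model
#'
#' @param object a `residual_model`.
#' @param covariates data.frame with the four covariate columns.
#' @param ... unused.
#' @return matrix `n x n_features` of model predictions.
#' @export
predict.residual_model <- function(object, covariates, ...) {
  X <- design_matrix(covariates, nrow(covariates))
  X %*% object$coefficients
}

#' Subtract the fitted covariate effects from features
#'
#' Residual = observed − (β0 + β_age·age + β_sex·sex + β_TIV·TIV + β_FS·FS),
#' feature-wise. The model is fitted on controls but applicable to any
#' subject.
#'
#' @param features matrix, list of volumes, or 4D array (same shape the model
#'   was fitted on).
#' @param covariates data.frame with the covariate columns, same subject
#'   order as `features`.
#' @param model a `residual_model` from [fit_residualizer()].
#' @return residual features in the same form as the input: a matrix, or a
#'   list of 3D residual arrays if volumes were given.
#' @export
apply_residualizer <- function(features, covariates, model) {
  as_list <- is.list(features)
  Y <- as_feature_matrix(features)
  if (ncol(Y) != ncol(model$coefficients))
    stop(sprintf("feature count (%d) does not match the fitted model (%d)",
                 ncol(Y), ncol(model$coefficients)), call. = FALSE)
  R <- Y - predict(model, covariates)
  if (as_list) {
    d <- attr(Y, "grid_dim")
    vs <- voxel_size(features[[1]])
    return(lapply(seq_len(nrow(R)), function(j)
      gm_volume(array(R[j, ], d), voxel_size_mm = vs, space_tag = "residual")))
  }
  R
}

#' Residualize a scalar feature (e.g. hippocampus volume)
#'
#' Fits the covariate model on the control subset and applies it to all
#' subjects, exactly as for the voxel grids.
#'
#' @param values numeric vector, one scalar per subject.
#' @param covariates data.frame with the covariate columns for all subjects.
#' @param control_mask logical vector marking the control subjects used for
#'   fitting.
#' @return list with `residuals` (numeric vector) and `model`
#'   (`residual_model`).
#' @export
residualize_scalar <- function(values, covariates, control_mask) {
  stopifnot(length(values) == nrow(covariates),
            length(control_mask) == length(values))
  m <- fit_residualizer(matrix(values[control_mask], ncol = 1),
                        covariates[control_mask, , drop = FALSE])
  res <- drop(apply_residualizer(matrix(values, ncol = 1), covariates, m))
  list(residuals = res, model = m)
}

#' Persist a residual model as a NIfTI coefficient stack + JSON sidecar
#'
#' The five coefficient maps (intercept, age, sex, TIV, field strength) are
#' stored as frames of a 4D NIfTI; the sidecar names the covariate order and
#' fit metadata. Only grid-shaped models can be written this way.
#'
#' @param model a `residual_model` fitted on volumes.
#' @param path output `.nii.gz` path.
#' @export
write_residual_model <- function(model, path) {
  fs <- model$feature_shape
  if (length(fs) != 3L)
    stop("only grid-shaped residual models are written as NIfTI", call. = FALSE)
  arr <- array(t(model$coefficients), c(fs, 5L))
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(list(covariates = model$covariates, fit_n = model$fit_n,
                            feature_shape = fs),
                       sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_residual_model
#' @export
read_residual_model <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  B <- t(matrix(as.numeric(img), prod(d[1:3]), d[4]))
  structure(list(coefficients = B, feature_shape = d[1:3],
                 fit_n = meta$fit_n, covariates = meta$covariates),
            class = "residual_model")
}
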