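#' Gray-matter volume container
#'
#' A `gm_volume` is a plain 3D numeric array of modulated gray-matter density
#' carrying the voxel size (mm, isotropic) and a free-text space tag as
#' attributes. Most functions in the package also accept bare 3D arrays, in
#' which case the default 1.5 mm voxel size is assumed.
#'
#' @param values 3D numeric array of voxel intensities (unitless density).
#' @param voxel_size_mm positive scalar isotropic voxel edge length in mm.
#' @param space_tag free-text description of the reference space.
#' @return A `gm_volume` object.
#' @examples
#' v <- gm_volume(array(runif(8^3), c(8, 8, 8)))
#' voxel_size(v)
#' @export
gm_volume <- function(values, voxel_size_mm = 1.5, space_tag = "MNI-like") {
  check_grid3d(values)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar", call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume contains non-finite values", call. = FALSE)
  structure(values,
            voxel_size_mm = as.numeric(voxel_size_mm),
            space_tag = space_tag,
            class = c("gm_volume", "array"))
}

#' @rdname gm_volume
#' @param x object to query.
#' @export
voxel_size <- function(x) {
  as.numeric(attr(x, "voxel_size_mm") %||% 1.5)
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("gm_volume %s @ %.3g mm (%s); range [%.4g, %.4g]\n",
              paste(dim(x), collapse = "x"), voxel_size(x),
              attr(x, "space_tag") %||% "?", min(x), max(x)))
  invisible(x)
}

#' Read and write single-frame NIfTI volumes
#'
#' Thin wrappers around RNifti. `write_volume()` stores doubles so a
#' write/read round trip preserves voxel values bit-exactly. Four-dimensional
#' files are rejected; anisotropic voxel sizes trigger a warning and the
#' smallest dimension is kept (the pipeline assumes isotropic grids).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [gm_volume()].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(gm_volume(array(rnorm(1000), c(10, 10, 10))), f)
#' v <- read_volume(f)
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a single-frame 3D NIfTI, got shape %s in %s",
                 paste(d, collapse = "x"), path), call. = FALSE)
  pd <- RNifti::pixdim(img)[seq_len(3)]
  vs <- pd[1]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) {
    warning(sprintf("non-isotropic voxels (%s); keeping smallest dimension",
                    paste(signif(pd, 4), collapse = "x")), call. = FALSE)
    vs <- min(pd)
  }
  gm_volume(array(as.numeric(img), d), voxel_size_mm = vs)
}

#' @rdname read_volume
#' @param volume 3D array or [gm_volume()].
#' @export
write_volume <- function(volume, path) {
  check_grid3d(volume)
  vs <- voxel_size(volume)
  arr <- array(as.numeric(volume), dim(volume))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vs, vs, vs)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write covariate tables
#'
#' The subject table is a TSV with the columns `subject_id`, `age` (years),
#' `sex` (0/1), `tiv` (total intracranial volume, ml), `field_strength`
#' (0 = 1.5T, 1 = 3T), and `diagnosis` (CN, MCI, or AD).
#'
#' @param path TSV file path.
#' @return `read_covariates()` returns a data.frame with the schema above.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "tiv", "field_strength", "diagnosis")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("covariate table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_records(df)
  df
}

#' @rdname read_covariates
#' @param records data.frame of subject records.
#' @export
write_covariates <- function(records, path) {
  validate_records(records)
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(records$age <= 0)) stop("age must be positive", call. = FALSE)
  if (any(records$tiv <= 0)) stop("TIV must be positive", call. = FALSE)
  if (!all(records$diagnosis %in% c("CN", "MCI", "AD")))
    stop("diagnosis must be one of CN, MCI, AD", call. = FALSE)
  if (!all(records$sex %in% c(0, 1)))
    stop("sex must be coded 0/1", call. = FALSE)
  if (!all(records$field_strength %in% c(0, 1)))
    stop("field_strength must be coded 0 (1.5T) / 1 (3T)", call. = FALSE)
  invisible(records)
}

# Stack a list of volumes (or a 4D array) into an n x n_voxel matrix.
stack_volumes <- function(volumes) {
  if (is.list(volumes)) {
    d <- dim(volumes[[1]])
    m <- t(vapply(volumes, function(v) {
      check_same_shape(v, volumes[[1]], c("volume", "first volume"))
      as.numeric(v)
    }, numeric(prod(d))))
    attr(m, "grid_dim") <- d
    return(m)
  }
  d <- dim(volumes)
  if (length(d) == 4L) {
    m <- t(matrix(as.numeric(volumes), prod(d[1:3]), d[4]))
    attr(m, "grid_dim") <- d[1:3]
    return(m)
  }
  stop("volumes must be a list of 3D arrays or a 4D array", call. = FALSE)
}
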