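#' Specification of a synthetic cohort
#'
#' Bundles everything the brain-phantom generator needs: group sizes, grid
#' shape, covariate sampling distributions, the true per-covariate intensity
#' slopes of the linear covariate model, the per-region/per-diagnosis
#' multiplicative atrophy attenuation, and the voxel noise level. The
#' defaults define the package's reference synthetic study conditions (see
#' the methods vignette): gray-matter-like density values around 0.2–0.8,
#' elderly covariate ranges, and hippocampus-dominant atrophy with the MCI
#' attenuation half of the AD attenuation.
#'
#' @param n_control,n_mci,n_ad group sizes (non-negative integers).
#' @param grid_shape 3 positive integers; default 40x40x48 (the full
#'   100x100x120 grid is supported but not the default).
#' @param age_range uniform sampling range for age in years.
#' @param sex_p probability of sex = 1.
#' @param tiv_mean,tiv_sd normal parameters for TIV in ml.
#' @param fs_p probability of field strength = 1 (3T).
#' @param covariate_slopes named numeric: intensity change per unit of
#'   `age` (years), `sex` (0/1), `tiv` (ml), `fs` (0/1), applied on brain
#'   voxels relative to the reference covariates (center of each
#'   distribution).
#' @param atrophy_regions named list mapping region name to
#'   `c(MCI = f, AD = f)` multiplicative attenuation fractions in `[0, 1)`.
#' @param noise_sd Gaussian voxel noise standard deviation (>= 0).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param seed integer seed controlling the whole cohort draw.
#' @return A `cohort_spec` list.
#' @examples
#' sp <- cohort_spec(n_control = 4, n_mci = 2, n_ad = 2,
#'                   grid_shape = c(20, 20, 24), seed = 7)
#' @export
cohort_spec <- function(n_control = 100L, n_mci = 50L, n_ad = 50L,
                        grid_shape = c(40L, 40L, 48L),
                        age_range = c(60, 85), sex_p = 0.5,
                        tiv_mean = 1450, tiv_sd = 130, fs_p = 0.7,
                        covariate_slopes = c(age = -0.004, sex = -0.02,
                                             tiv = 2e-4, fs = 0.01),
                        atrophy_regions = list(
                          hippocampus = c(MCI = 0.2, AD = 0.4),
                          temporal    = c(MCI = 0.1, AD = 0.2)),
                        noise_sd = 0.1, voxel_size_mm = 1.5, seed = 1L) {
  counts <- c(n_control, n_mci, n_ad)
  if (any(counts < 0)) stop("group sizes must be non-negative", call. = FALSE)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (r in names(atrophy_regions)) {
    f <- atrophy_regions[[r]]
    if (any(f < 0) || any(f >= 1))
      stop("attenuation fractions must lie in [0, 1)", call. = FALSE)
    if (all(c("MCI", "AD") %in% names(f)) && f[["MCI"]] > f[["AD"]])
      stop("MCI attenuation must not exceed AD attenuation (region ", r, ")",
           call. = FALSE)
  }
  structure(list(n_control = as.integer(n_control), n_mci = as.integer(n_mci),
                 n_ad = as.integer(n_ad), grid_shape = as.integer(grid_shape),
                 age_range = age_range, sex_p = sex_p, tiv_mean = tiv_mean,
                 tiv_sd = tiv_sd, fs_p = fs_p,
                 covariate_slopes = covariate_slopes,
                 atrophy_regions = atrophy_regions, noise_sd = noise_sd,
                 voxel_size_mm = voxel_size_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Reference covariates about which the slopes act (distribution centers),
# so that control volumes stay near the base template.
reference_covariates <- function(spec) {
  c(age = mean(spec$age_range), sex = spec$sex_p,
    tiv = spec$tiv_mean, fs = spec$fs_p)
}

#' Smooth ellipsoidal base intensity template
#'
#' High intensity inside an ellipsoid spanning ~84% of each grid dimension,
#' zero outside, softened by separable Gaussian smoothing — a crude stand-in
#' for a gray-matter density map. Deterministic given the grid shape.
#'
#' @param grid_shape 3 positive integers.
#' @param peak interior intensity before smoothing.
#' @param smooth_sd Gaussian smoothing sd in voxels.
#' @return 3D numeric array.
#' @export
base_template <- function(grid_shape, peak = 0.8, smooth_sd = 1.5) {
  grid_shape <- as.integer(grid_shape)
  ctr <- (grid_shape + 1) / 2
  semi <- 0.42 * grid_shape
  d1 <- ((seq_len(grid_shape[1]) - ctr[1]) / semi[1])^2
  d2 <- ((seq_len(grid_shape[2]) - ctr[2]) / semi[2])^2
  d3 <- ((seq_len(grid_shape[3]) - ctr[3]) / semi[3])^2
  r2 <- outer(outer(d1, d2, `+`), d3, `+`)
  tpl <- array(peak * (r2 <= 1), grid_shape)
  gauss_smooth3d(tpl, smooth_sd)
}

# Separable 3D Gaussian smoothing (zero-padded borders).
gauss_smooth3d <- function(x, sd) {
  if (sd <= 0) return(x)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r):r)^2 / (2 * sd^2)); k <- k / sum(k)
  d <- dim(x)
  smooth_axis <- function(a, axis) {
    m <- apply(a, setdiff(1:3, axis), function(v) {
      as.numeric(stats::filter(c(rep(0, r), v, rep(0, r)), k, sides = 2))[(r + 1):(r + length(v))]
    })
    # apply returns axis-first; permute back
    aperm(array(m, c(d[axis], d[setdiff(1:3, axis)])),
          order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) x <- smooth_axis(x, ax)
  x
}

# Voxels that respond to covariates; template values above this threshold
# cannot be driven below zero by the covariate perturbations, keeping the
# noiseless linear model exact (no clipping).
brain_mask_from_template <- function(tpl) tpl > 0.2

default_region_specs <- function(grid_shape) {
  g <- as.numeric(grid_shape)
  sc <- g / c(40, 40, 48)  # positions scale with the grid
  reg <- function(name, center, semi) {
    s <- pmax(2, round(semi * sc))
    # keep the whole ellipsoid inside the grid on small grids
    ctr <- pmin(pmax(round(center * sc), s + 1), g - s)
    list(name = name, type = "ellipsoid", center = ctr, semi = s)
  }
  list(reg("hippocampus", c(20, 18, 17), c(4, 5, 4)),
       reg("temporal", c(10, 16, 16), c(4, 5, 5)),
       reg("parietal", c(20, 28, 32), c(5, 5, 5)))
}

#' Simulate one subject's gray-matter volume
#'
#' Voxel value = base template + per-covariate slopes times the centered
#' covariates (brain voxels only) + Gaussian noise, then multiplied by
#' `(1 - attenuation)` inside the atrophy regions configured for the
#' subject's diagnosis, and clipped at zero.
#'
#' @param atlas a `region_atlas` on the spec's grid.
#' @param record one-row data.frame (or list) with `age`, `sex`, `tiv`,
#'   `field_strength`, `diagnosis`.
#' @param spec a [cohort_spec()].
#' @param seed integer seed for the voxel noise.
#' @param template optional precomputed [base_template()] for the grid.
#' @return a [gm_volume()].
#' @export
simulate_subject <- function(atlas, record, spec, seed = 1L, template = NULL) {
  diag <- as.character(record$diagnosis)
  if (!diag %in% c("CN", "MCI", "AD"))
    stop("unknown diagnosis: ", diag, call. = FALSE)
  tpl <- template %||% base_template(spec$grid_shape)
  mask <- brain_mask_from_template(tpl)
  ref <- reference_covariates(spec)
  sl <- spec$covariate_slopes
  shift <- sl[["age"]] * (record$age - ref[["age"]]) +
    sl[["sex"]] * (record$sex - ref[["sex"]]) +
    sl[["tiv"]] * (record$tiv - ref[["tiv"]]) +
    sl[["fs"]]  * (record$field_strength - ref[["fs"]])
  vol <- tpl
  vol[mask] <- vol[mask] + shift
  if (spec$noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    vol <- vol + array(rnorm(length(vol), sd = spec$noise_sd), dim(vol))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (diag != "CN") {
    for (r in names(spec$atrophy_regions)) {
      f <- spec$atrophy_regions[[r]]
      att <- if (diag %in% names(f)) f[[diag]] else 0
      if (att > 0) {
        rm_ <- atlas_region_mask(atlas, r)
        vol[rm_] <- vol[rm_] * (1 - att)
      }
    }
  }
  vol[vol < 0] <- 0
  gm_volume(vol, voxel_size_mm = spec$voxel_size_mm)
}

#' Simulate a full cohort
#'
#' Draws covariates i.i.d. from the spec's distributions, generates one
#' volume per subject with [simulate_subject()], and builds the default
#' three-region atlas (hippocampus, temporal, parietal) on the grid.
#' Fully reproducible for a fixed spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @param atlas optional `region_atlas`; the default layout is used if NULL.
#' @return list with `volumes` (list of [gm_volume()]), `records`
#'   (data.frame: subject_id, age, sex, tiv, field_strength, diagnosis) and
#'   `atlas`.
#' @export
simulate_cohort <- function(spec, atlas = NULL) {
  n <- spec$n_control + spec$n_mci + spec$n_ad
  if (n == 0L) stop("cohort has zero subjects", call. = FALSE)
  atlas <- atlas %||% make_atlas(spec$grid_shape,
                                 default_region_specs(spec$grid_shape),
                                 voxel_size_mm = spec$voxel_size_mm)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  records <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    sex = rbinom(n, 1, spec$sex_p),
    tiv = rnorm(n, spec$tiv_mean, spec$tiv_sd),
    field_strength = rbinom(n, 1, spec$fs_p),
    diagnosis = rep(c("CN", "MCI", "AD"),
                    c(spec$n_control, spec$n_mci, spec$n_ad)),
    stringsAsFactors = FALSE)
  records$tiv <- pmax(records$tiv, 1)  # guard the >0 invariant
  subject_seeds <- (as.double(spec$seed) * 1000003 + seq_len(n)) %% 2147483647
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tpl <- base_template(spec$grid_shape)
  volumes <- lapply(seq_len(n), function(j)
    simulate_subject(atlas, records[j, ], spec, seed = subject_seeds[j],
                     template = tpl))
  list(volumes = volumes, records = records, atlas = atlas)
}

#' Write a simulated cohort to disk
#'
#' Volumes as NIfTI (`<subject_id>.nii.gz`), the subject table as TSV, the
#' atlas as NIfTI + JSON sidecar, and the spec as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @param spec the [cohort_spec()] used (stored as JSON).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(cohort$volumes))
    write_volume(cohort$volumes[[j]],
                 file.path(dir, paste0(cohort$records$subject_id[j], ".nii.gz")))
  write_covariates(cohort$records, file.path(dir, "covariates.tsv"))
  write_atlas(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
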