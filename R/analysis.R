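#' Sum of relevance inside a region mask
#'
#' @param map a `relevance_map` or 3D array.
#' @param mask logical 3D array on the same grid.
#' @return scalar sum over masked voxels.
#' @export
region_relevance_sum <- function(map, mask) {
  v <- if (inherits(map, "relevance_map")) map$values else map
  check_same_shape(v, mask, c("map", "mask"))
  sum(v[mask])
}

#' Region volume from a modulated density map
#'
#' Sum of the gray-matter density over the mask times the voxel volume;
#' with modulated maps this is the region's tissue volume. Reported in ml.
#'
#' @param volume 3D array or [gm_volume()] of modulated density.
#' @param mask logical 3D array.
#' @param voxel_size_mm isotropic voxel size; taken from the volume when
#'   available.
#' @return volume in ml.
#' @examples
#' v <- gm_volume(array(1, c(10, 10, 10)))
#' region_volume_ml(v, array(TRUE, c(10, 10, 10)))  # 1000 * 1.5^3 / 1000
#' @export
region_volume_ml <- function(volume, mask, voxel_size_mm = NULL) {
  check_same_shape(volume, mask, c("volume", "mask"))
  vs <- voxel_size_mm %||% voxel_size(volume)
  sum(volume[mask]) * vs^3 / 1000
}

#' Extract supra-threshold relevance clusters
#'
#' Connected components of the voxel set above the relevance threshold,
#' under face (6) or full (26) adjacency, filtered by a minimum cluster
#' size — the computation behind interactive cluster displays, where the two
#' thresholds suppress visual noise from isolated high-relevance voxels.
#'
#' @param map `relevance_map` or 3D array.
#' @param threshold relevance threshold; voxels with value >= threshold form
#'   the supra-threshold set.
#' @param min_size minimum cluster size in voxels (>= 1).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @param voxel_size_mm voxel size for the ml conversion.
#' @return A `cluster_set`: `clusters` data.frame (cluster_id, size_voxels,
#'   volume_ml, peak_relevance, peak_x/y/z, all member voxels accessible via
#'   `labels`), `labels` (3D integer array, 0 outside clusters),
#'   `size_histogram` (sizes of all components before the min_size filter),
#'   and the thresholds used.
#' @export
extract_clusters <- function(map, threshold, min_size = 1L, connectivity = 6L,
                             voxel_size_mm = NULL) {
  v <- if (inherits(map, "relevance_map")) map$values else map
  vs <- voxel_size_mm %||%
    (if (inherits(map, "relevance_map")) map$voxel_size_mm else 1.5)
  stopifnot(!is.na(threshold), min_size >= 1L, connectivity %in% c(6L, 26L))
  mask <- v >= threshold
  lab <- label_components_cpp(as.logical(mask), dim(v), as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  out_lab <- array(0L, dim(v))
  rows <- list()
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) {
      sel <- lab == keep[i]
      out_lab[sel] <- i
      idx <- which(sel)
      peak <- idx[which.max(v[idx])]
      pc <- arrayInd(peak, dim(v))
      rows[[i]] <- data.frame(cluster_id = i, size_voxels = sizes[keep[i]],
                              volume_ml = sizes[keep[i]] * vs^3 / 1000,
                              peak_relevance = v[peak],
                              peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), size_voxels = integer(),
               volume_ml = numeric(), peak_relevance = numeric(),
               peak_x = integer(), peak_y = integer(), peak_z = integer())
  structure(list(clusters = clusters, labels = out_lab,
                 size_histogram = sizes[sizes > 0],
                 threshold_used = threshold, min_size_used = as.integer(min_size),
                 connectivity = as.integer(connectivity)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) (threshold %.4g, min size %d, %d-connectivity)\n",
              nrow(x$clusters), x$threshold_used, x$min_size_used,
              x$connectivity))
  if (nrow(x$clusters)) print(head(x$clusters, 10))
  invisible(x)
}

#' Write a cluster table as TSV
#'
#' @param clusters a `cluster_set`.
#' @param path output path.
#' @param atlas optional `region_atlas` used to annotate each peak with its
#'   region name.
#' @export
write_cluster_table <- function(clusters, path, atlas = NULL) {
  tab <- clusters$clusters
  if (!is.null(atlas) && nrow(tab))
    tab$region <- vapply(seq_len(nrow(tab)), function(i)
      atlas_lookup(c(tab$peak_x[i], tab$peak_y[i], tab$peak_z[i]), atlas),
      character(1))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-slice positive/negative relevance profile
#'
#' For every slice along the chosen anatomical axis, the sums of positive
#' and negative relevance are returned separately — the data behind
#' slice-navigation guides in relevance viewers.
#'
#' @param map `relevance_map` or 3D array.
#' @param axis `"sagittal"` (1), `"coronal"` (2) or `"axial"` (3).
#' @return data.frame with `slice`, `positive_sum`, `negative_sum`.
#' @export
slice_relevance_profile <- function(map, axis = c("sagittal", "coronal", "axial")) {
  v <- if (inherits(map, "relevance_map")) map$values else map
  ax <- if (is.character(axis)) {
    axis <- match.arg(axis)
    .axis_names[[axis]]
  } else as.integer(axis)
  if (!ax %in% 1:3) stop("axis must be sagittal/coronal/axial (1/2/3)", call. = FALSE)
  pos <- apply(pmax(v, 0), ax, sum)
  neg <- apply(pmin(v, 0), ax, sum)
  data.frame(slice = seq_along(pos), positive_sum = pos, negative_sum = neg)
}

#' Occlusion sensitivity scan
#'
#' Slides a cube across the volume; inside the cube, voxel intensities are
#' multiplied by `(1 - attenuation)` (default 50% reduction — simulated
#' focal gray-matter atrophy) and the model is re-run. For each cube
#' position the target-class probability and pre-softmax score are recorded,
#' and optionally the total relevance of the perturbed scan. Cube positions
#' are clipped so the cube lies fully inside the grid. With the default
#' 20-voxel cube at 1.5 mm the physical edge is 30 mm (reported in the
#' result).
#'
#' @param network a `cnn3d` (or any object with a [predict()] method
#'   returning class probabilities and, for `type = "logit"`, scores).
#' @param volume input volume.
#' @param cube_edge cube edge length in voxels.
#' @param attenuation intensity reduction fraction inside the cube, in
#'   `[0, 1]`.
#' @param stride lattice step between cube positions (voxels).
#' @param target_class class whose probability is tracked (default: disease
#'   class).
#' @param compute_relevance also compute the total relevance of each
#'   perturbed scan (slow; requires a `cnn3d`).
#' @param lrp an [lrp_config()] for the relevance computation.
#' @param preprocess optional function applied to the (occluded) volume
#'   before prediction — typically the covariate residualization, so that
#'   atrophy is simulated on the raw density map while the model still sees
#'   residual images. Also applied to the unoccluded baseline.
#' @return An `occlusion_result`: `probability_grid`, `logit_grid`,
#'   `total_relevance_grid` (or NULL), `positions` (cube centers),
#'   `cube_edge_voxels`, `cube_edge_mm`, `attenuation`, `stride`, and the
#'   unoccluded `baseline` probability/logit.
#' @export
occlusion_scan <- function(network, volume, cube_edge = 20L, attenuation = 0.5,
                           stride = 4L, target_class = NULL,
                           compute_relevance = FALSE, lrp = lrp_config(),
                           preprocess = NULL) {
  check_grid3d(volume)
  d <- dim(volume)
  cube_edge <- as.integer(cube_edge)
  if (any(cube_edge > d))
    stop(sprintf("cube edge %d exceeds grid %s", cube_edge,
                 paste(d, collapse = "x")), call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  labels <- if (inherits(network, "cnn3d")) network$spec$class_labels
            else c("CN", "AD")
  target_class <- target_class %||% labels[length(labels)]
  tci <- if (is.numeric(target_class)) as.integer(target_class)
         else match(target_class, labels)
  starts <- lapply(d, function(n) {
    s <- seq(1L, n - cube_edge + 1L, by = as.integer(stride))
    unique(c(s, n - cube_edge + 1L))  # always include the far edge
  })
  np <- vapply(starts, length, integer(1))
  prob <- logit <- array(NA_real_, np)
  totrel <- if (compute_relevance) array(NA_real_, np)
  prep <- if (is.null(preprocess)) identity else preprocess
  base_in <- prep(volume)
  p0 <- predict(network, base_in, type = "prob")
  l0 <- predict(network, base_in, type = "logit")
  for (i3 in seq_len(np[3])) for (i2 in seq_len(np[2])) for (i1 in seq_len(np[1])) {
    s <- c(starts[[1]][i1], starts[[2]][i2], starts[[3]][i3])
    occ <- volume
    rng1 <- s[1]:(s[1] + cube_edge - 1L)
    rng2 <- s[2]:(s[2] + cube_edge - 1L)
    rng3 <- s[3]:(s[3] + cube_edge - 1L)
    occ[rng1, rng2, rng3] <- occ[rng1, rng2, rng3] * (1 - attenuation)
    occ <- prep(occ)
    prob[i1, i2, i3] <- predict(network, occ, type = "prob")[tci]
    logit[i1, i2, i3] <- predict(network, occ, type = "logit")[tci]
    if (compute_relevance)
      totrel[i1, i2, i3] <- sum(relevance_map(network, occ, target_class = tci,
                                              config = lrp)$values)
  }
  vs <- voxel_size(volume)
  structure(list(probability_grid = prob, logit_grid = logit,
                 total_relevance_grid = totrel,
                 positions = lapply(starts, function(s) s + (cube_edge - 1L) / 2),
                 cube_edge_voxels = cube_edge, cube_edge_mm = cube_edge * vs,
                 attenuation = attenuation, stride = as.integer(stride),
                 target_class = labels[tci],
                 baseline = list(prob = p0[tci], logit = l0[tci])),
            class = "occlusion_result")
}

#' @export
print.occlusion_result <- function(x, ...) {
  cat(sprintf("occlusion_result: %s positions, cube %d voxels = %g mm, attenuation %g\n",
              paste(dim(x$probability_grid), collapse = "x"),
              x$cube_edge_voxels, x$cube_edge_mm, x$attenuation))
  cat(sprintf("  baseline P(%s) = %.3f; occluded range [%.3f, %.3f]\n",
              x$target_class, x$baseline$prob,
              min(x$probability_grid), max(x$probability_grid)))
  invisible(x)
}
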