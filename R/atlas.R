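#' Build a labelled region atlas on a voxel grid
#'
#' Creates an integer-labelled 3D grid naming anatomical stand-in regions,
#' the synthetic analogue of an anatomical parcellation in standard space.
#' Regions are axis-aligned ellipsoids or boxes; they must be pairwise
#' disjoint and lie fully inside the grid, and at least one region must be
#' named `"hippocampus"` so that downstream volumetry and relevance
#' aggregation have their reference structure.
#'
#' @param grid_shape integer vector of 3 positive grid dimensions.
#' @param region_specs list of region definitions, each a list with `name`,
#'   `type` (`"ellipsoid"` or `"box"`), `center` (voxel coordinates, 1-based)
#'   and `semi` (semi-axes in voxels; for a box, half edge lengths). Labels
#'   are assigned 1, 2, ... in list order.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param seed unused randomness hook kept for interface stability; the
#'   construction is deterministic.
#' @return A `region_atlas`: list with `labels` (3D integer array, 0 =
#'   background), `region_names` (named character, names are labels) and
#'   `voxel_size_mm`.
#' @examples
#' atl <- make_atlas(c(20, 20, 20),
#'   list(list(name = "hippocampus", type = "ellipsoid",
#'             center = c(10, 10, 10), semi = c(3, 3, 3))))
#' table(atl$labels)
#' @export
make_atlas <- function(grid_shape, region_specs, voxel_size_mm = 1.5, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  labels <- array(0L, grid_shape)
  nm <- character(0)
  if (length(region_specs)) {
    for (k in seq_along(region_specs)) {
      rs <- region_specs[[k]]
      if (is.null(rs$name)) stop("region ", k, " has no name", call. = FALSE)
      mask <- region_mask(grid_shape, rs)
      if (!any(mask))
        stop("region '", rs$name, "' contains no voxels", call. = FALSE)
      if (any(rs$center - rs$semi < 1) || any(rs$center + rs$semi > grid_shape))
        stop("region '", rs$name, "' extends outside the grid", call. = FALSE)
      if (any(labels[mask] != 0L))
        stop("region '", rs$name, "' overlaps region '",
             nm[max(labels[mask])], "'", call. = FALSE)
      labels[mask] <- k
      nm <- c(nm, rs$name)
    }
  }
  if (length(nm) && !("hippocampus" %in% nm))
    warning("atlas has no region named 'hippocampus'", call. = FALSE)
  names(nm) <- as.character(seq_along(nm))
  structure(list(labels = labels, region_names = nm,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "region_atlas")
}

region_mask <- function(grid_shape, rs) {
  type <- match.arg(rs$type %||% "ellipsoid", c("ellipsoid", "box"))
  ctr <- as.numeric(rs$center); semi <- as.numeric(rs$semi)
  stopifnot(length(ctr) == 3L, length(semi) == 3L, all(semi > 0))
  i1 <- seq_len(grid_shape[1]); i2 <- seq_len(grid_shape[2]); i3 <- seq_len(grid_shape[3])
  if (type == "ellipsoid") {
    d1 <- ((i1 - ctr[1]) / semi[1])^2
    d2 <- ((i2 - ctr[2]) / semi[2])^2
    d3 <- ((i3 - ctr[3]) / semi[3])^2
    outer(outer(d1, d2, `+`), d3, `+`) <= 1
  } else {
    m1 <- abs(i1 - ctr[1]) <= semi[1]
    m2 <- abs(i2 - ctr[2]) <= semi[2]
    m3 <- abs(i3 - ctr[3]) <= semi[3]
    outer(outer(m1, m2, `&`), m3, `&`)
  }
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas %s @ %.3g mm, %d regions\n",
              paste(dim(x$labels), collapse = "x"), x$voxel_size_mm,
              length(x$region_names)))
  for (l in seq_along(x$region_names))
    cat(sprintf("  %2d %-16s %6d voxels\n", l, x$region_names[l],
                sum(x$labels == l)))
  invisible(x)
}

#' Binary mask of one atlas region
#'
#' @param atlas a `region_atlas`.
#' @param region region name (or integer label).
#' @return logical 3D array.
#' @export
atlas_region_mask <- function(atlas, region) {
  lab <- if (is.numeric(region)) as.integer(region) else {
    hit <- which(atlas$region_names == region)
    if (!length(hit)) stop("unknown region: ", region, call. = FALSE)
    as.integer(names(atlas$region_names)[hit])
  }
  array(atlas$labels %in% lab, dim(atlas$labels))
}

#' Region name at a voxel coordinate
#'
#' @param coordinate integer vector of 3 (1-based voxel indices).
#' @param atlas a `region_atlas`.
#' @return the region name, or `"background"` for unlabelled voxels.
#' @export
atlas_lookup <- function(coordinate, atlas) {
  coordinate <- as.integer(coordinate)
  d <- dim(atlas$labels)
  if (length(coordinate) != 3L || any(coordinate < 1L) || any(coordinate > d))
    stop(sprintf("coordinate (%s) outside grid %s",
                 paste(coordinate, collapse = ","), paste(d, collapse = "x")),
         call. = FALSE)
  l <- atlas$labels[coordinate[1], coordinate[2], coordinate[3]]
  if (l == 0L) "background" else unname(atlas$region_names[as.character(l)])
}

#' Write an atlas as NIfTI
#'
#' Labels go to a NIfTI volume; region names to a JSON sidecar next to it.
#' @param path output `.nii.gz` path.
#' @rdname make_atlas
#' @param atlas a `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  img <- RNifti::asNifti(array(as.numeric(atlas$labels), dim(atlas$labels)))
  RNifti::pixdim(img) <- rep(atlas$voxel_size_mm, 3)
  RNifti::writeNifti(img, path, datatype = "int16")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(as.list(atlas$region_names), sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname make_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  nm <- unlist(jsonlite::read_json(sidecar))
  structure(list(labels = array(as.integer(img), dim(img)),
                 region_names = nm,
                 voxel_size_mm = RNifti::pixdim(img)[1]),
            class = "region_atlas")
}
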