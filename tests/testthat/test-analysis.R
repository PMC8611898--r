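test_that("region relevance sums match a brute-force masked loop", {
  set.seed(1)
  v <- array(rnorm(10 * 10 * 12), c(10, 10, 12))
  mask <- array(runif(1200) > 0.7, c(10, 10, 12))
  loop <- 0
  for (i in which(mask)) loop <- loop + v[i]
  expect_equal(region_relevance_sum(v, mask), loop, tolerance = 1e-12)
  expect_identical(region_relevance_sum(array(0, dim(v)), mask), 0)
  expect_equal(region_relevance_sum(v, array(TRUE, dim(v))), sum(v))
  expect_error(region_relevance_sum(v, mask[1:5, , ]), "shape")
})

test_that("region volume converts density to ml through the voxel volume", {
  v <- gm_volume(array(1, c(10, 10, 10)), voxel_size_mm = 1.5)
  full <- array(TRUE, c(10, 10, 10))
  expect_equal(region_volume_ml(v, full), 1000 * 1.5^3 / 1000)  # 3.375 ml
  expect_identical(region_volume_ml(v, array(FALSE, dim(v))), 0)
  half <- gm_volume(array(0.5, c(10, 10, 10)), voxel_size_mm = 1.5)
  expect_equal(region_volume_ml(half, full), region_volume_ml(v, full) / 2)
})

test_that("cluster extraction filters by threshold and size", {
  m <- array(0, c(12, 12, 12))
  # blob A: 12 voxels (face-connected), blob B: 5 voxels, separated
  m[2:5, 2:4, 2] <- 1      # 12 voxels
  m[9:10, 9, c(5, 6)] <- 1 # 4 voxels
  m[9, 9, 7] <- 1          # +1 connected -> 5
  cs <- extract_clusters(m, threshold = 0.5, min_size = 10)
  expect_identical(nrow(cs$clusters), 1L)
  expect_identical(cs$clusters$size_voxels, 12L)
  expect_setequal(cs$size_histogram, c(12L, 5L))
  # threshold above the maximum: empty set
  expect_identical(nrow(extract_clusters(m, threshold = 2)$clusters), 0L)
  # min_size 1, threshold below min on an all-positive map: one full cluster
  cs2 <- extract_clusters(array(1, c(4, 4, 4)), threshold = -Inf, min_size = 1)
  expect_identical(nrow(cs2$clusters), 1L)
  expect_identical(cs2$clusters$size_voxels, 64L)
})

test_that("components match a union-find oracle for 6 and 26 connectivity", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- array(runif(10 * 9 * 8) > 0.65, c(10, 9, 8))
    for (conn in c(6L, 26L)) {
      lab <- relmap3d:::label_components_cpp(as.logical(m), dim(m), conn)
      ref <- brute_components(m, conn)
      # same partition (label ids may differ): compare via cross-tabulation
      expect_identical(max(lab), max(ref))
      tab <- table(lab[m], ref[m])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  }
})

test_that("cluster size accounting and peak statistics are consistent", {
  set.seed(4)
  v <- array(rnorm(16^3), c(16, 16, 16))
  cs <- extract_clusters(v, threshold = 1.2, min_size = 1, connectivity = 26)
  expect_identical(sum(cs$clusters$size_voxels), sum(v >= 1.2))
  if (nrow(cs$clusters)) {
    top <- cs$clusters[1, ]
    expect_equal(v[top$peak_x, top$peak_y, top$peak_z], top$peak_relevance)
    expect_gte(top$peak_relevance, 1.2)
    expect_equal(top$volume_ml, top$size_voxels * 1.5^3 / 1000)
  }
})

test_that("slice profiles split positive and negative relevance per slice", {
  set.seed(5)
  v <- array(rnorm(8 * 9 * 10), c(8, 9, 10))
  for (ax in c("sagittal", "coronal", "axial")) {
    p <- slice_relevance_profile(v, ax)
    i <- relmap3d:::.axis_names[[ax]]
    expect_identical(nrow(p), dim(v)[i])
    # loop oracle on one slice
    k <- 3L
    sl <- switch(i, v[k, , ], v[, k, ], v[, , k])
    expect_equal(p$positive_sum[k], sum(sl[sl > 0]), tolerance = 1e-12)
    expect_equal(p$negative_sum[k], sum(sl[sl < 0]), tolerance = 1e-12)
    # partition: pos + neg over slices equals the total sum
    expect_equal(sum(p$positive_sum + p$negative_sum), sum(v), tolerance = 1e-10)
  }
  nonneg <- abs(v)
  expect_true(all(slice_relevance_profile(nonneg, "axial")$negative_sum == 0))
  expect_error(slice_relevance_profile(v, "diagonal"),
               "sagittal|axis")
})

test_that("occlusion with zero attenuation reproduces the baseline and
           reports the physical cube edge", {
  net <- build_network(network_spec(c(24L, 24L, 24L)), seed = 1)
  v <- gm_volume(random_volume(c(24, 24, 24), seed = 2, mean = 0.5, sd = 0.1))
  occ0 <- occlusion_scan(net, v, cube_edge = 20L, attenuation = 0, stride = 4L)
  expect_equal(occ0$cube_edge_mm, 30)
  expect_true(all(abs(occ0$probability_grid - occ0$baseline$prob) < 1e-10))
  expect_error(occlusion_scan(net, v, cube_edge = 30L), "exceeds")
})

test_that("occlusion logit drop is exact for a linear mass-summing model", {
  # toy model whose disease logit is the total intensity inside a fixed
  # region M; occluding a cube that covers mass m of M lowers it by 0.5 m
  region <- array(FALSE, c(16, 16, 16)); region[4:9, 4:9, 4:9] <- TRUE
  toy <- structure(list(region = region), class = "toy_mass_model")
  assign("predict.toy_mass_model",
         function(object, newdata, type = "prob", ...) {
           logit <- sum(newdata[object$region])
           p <- exp(c(0, logit)); p <- p / sum(p)
           out <- if (type == "logit") c(CN = 0, AD = logit) else
             c(CN = p[1], AD = p[2])
           out
         }, envir = globalenv())
  on.exit(rm("predict.toy_mass_model", envir = globalenv()), add = TRUE)
  v <- gm_volume(array(1, c(16, 16, 16)))
  occ <- occlusion_scan(toy, v, cube_edge = 8L, attenuation = 0.5, stride = 4L)
  # cube starting at (1,1,1) overlaps region over 4:8^3 -> mass 125... the
  # overlap of cube [s, s+7] with region [4, 9] per axis
  base <- sum(v[region])
  ov <- function(s) max(0, min(s + 7, 9) - max(s, 4) + 1)
  for (i in seq_along(occ$positions[[1]])) {
    sx <- occ$positions[[1]][i] - 3.5
    expect_equal(occ$logit_grid[i, 1, 1],
                 base - 0.5 * ov(sx) * ov(1) * ov(1),
                 tolerance = 1e-9)
  }
})

test_that("simulated focal atrophy raises the disease probability more when
           the cube touches informative regions", {
  run <- acceptance_runs()[[1]]
  cn <- which(!run$test_idx & run$cohort$records$diagnosis == "CN")[1]
  # atrophy acts on the raw density map; the model sees residual images
  pred <- array(predict(run$residual_model,
                        run$cohort$records[cn, , drop = FALSE])[1, ],
                dim(run$cohort$volumes[[cn]]))
  occ <- occlusion_scan(run$model, run$cohort$volumes[[cn]],
                        cube_edge = 10L, attenuation = 0.5, stride = 5L,
                        preprocess = function(v) v - pred)
  dprob <- occ$probability_grid - occ$baseline$prob
  # label each cube position by overlap with the atrophy-informative regions
  info <- atlas_region_mask(run$cohort$atlas, "hippocampus") |
    atlas_region_mask(run$cohort$atlas, "temporal")
  lab <- array(FALSE, dim(dprob))
  for (i3 in seq_along(occ$positions[[3]]))
    for (i2 in seq_along(occ$positions[[2]]))
      for (i1 in seq_along(occ$positions[[1]])) {
        s <- c(occ$positions[[1]][i1], occ$positions[[2]][i2],
               occ$positions[[3]][i3]) - 4.5
        lab[i1, i2, i3] <- any(info[s[1]:(s[1] + 9), s[2]:(s[2] + 9),
                                    s[3]:(s[3] + 9)])
      }
  expect_gt(sum(lab), 3)
  expect_gt(sum(!lab), 3)
  wt <- stats::wilcox.test(dprob[lab], dprob[!lab], alternative = "greater")
  expect_lt(wt$p.value, 0.05)
})

test_that("cluster tables annotate peaks with atlas regions", {
  atl <- make_atlas(c(16L, 16L, 16L),
                    list(list(name = "hippocampus", type = "ellipsoid",
                              center = c(8, 8, 8), semi = c(4, 4, 4))))
  v <- array(0, c(16, 16, 16)); v[7:9, 7:9, 7:9] <- 1
  cs <- extract_clusters(v, threshold = 0.5, min_size = 1)
  f <- tempfile(fileext = ".tsv")
  write_cluster_table(cs, f, atlas = atl)
  tab <- read.delim(f)
  expect_identical(tab$region[1], "hippocampus")
})
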