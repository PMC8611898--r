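test_that("class weights follow 0.5 n / n_i", {
  w <- compute_class_weights(c(CN = 254, AD = 409))
  expect_equal(round(unname(w), 2), c(1.31, 0.81))
  expect_equal(unname(compute_class_weights(c(a = 30, b = 30))), c(1, 1))
  expect_equal(unname(compute_class_weights(c(A = 10, B = 40))), c(2.5, 0.625))
  expect_error(compute_class_weights(c(A = 0, B = 5)), "positive")
})

test_that("augmentation yields exactly 14 pairwise distinct variants", {
  v <- random_volume(c(12, 12, 14), seed = 1)
  vars <- augment_variants(v, shift = 3L)
  expect_length(vars, 14L)
  expect_identical(vars[[1]], v)
  keys <- vapply(vars, function(a) paste(head(signif(as.numeric(a), 7), 500),
                                         collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("flip is an involution and translation moves single voxels exactly", {
  v <- random_volume(c(12, 12, 14), seed = 2)
  flip <- relmap3d:::augment_apply(v, 8L, shift = 3L)  # variant 8 = pure flip
  flip2 <- relmap3d:::augment_apply(flip, 8L, shift = 3L)
  expect_identical(flip2, v)
  # single nonzero voxel translated +shift along x lands at p + (shift,0,0)
  z <- array(0, c(15, 12, 12)); z[3, 5, 6] <- 1
  t1 <- relmap3d:::augment_apply(z, 2L, shift = 10L)  # +x translation
  expect_equal(t1[13, 5, 6], 1)
  expect_equal(sum(t1), 1)
  # vacated voxels are zero-filled
  t2 <- relmap3d:::augment_apply(z, 3L, shift = 10L)  # -x translation
  expect_equal(sum(t2), 0)  # voxel shifted out of the grid
})

test_that("stratified folds stratify on the 3-class label with size balance", {
  diag <- rep(c("CN", "MCI", "AD"), c(254, 220, 189))
  f <- stratified_folds(diag, k = 10, seed = 1)
  expect_identical(sort(unique(f)), 1:10)
  sizes <- table(f)
  expect_true(all(sizes >= 66 & sizes <= 67))
  for (g in c("CN", "MCI", "AD")) {
    per <- table(f[diag == g])
    expect_lte(max(per) - min(per), 1)
  }
  per_cn <- table(f[diag == "CN"])
  expect_true(all(per_cn %in% c(25, 26)))
  expect_true(all(table(f[diag == "MCI"]) == 22))
  expect_true(all(table(f[diag == "AD"]) %in% c(18, 19)))
  expect_identical(f, stratified_folds(diag, k = 10, seed = 1))
  expect_error(stratified_folds(diag, k = 1), ">= 2")
  expect_error(stratified_folds(rep(c("CN", "MCI", "AD"), c(5, 30, 30)), k = 10),
               "stratum")
})

test_that("train_fold honors its contract on a miniature task", {
  spec <- small_cohort_spec(seed = 51L, n = c(12L, 6L, 6L))
  cohort <- simulate_cohort(spec)
  folds <- stratified_folds(cohort$records, k = 3L, seed = 51L)
  tr <- list(volumes = cohort$volumes[folds != 1L],
             records = cohort$records[folds != 1L, , drop = FALSE])
  te <- list(volumes = cohort$volumes[folds == 1L],
             records = cohort$records[folds == 1L, , drop = FALSE])
  cfg <- train_config(epochs = 2L, learning_rate = 1e-3, seed = 5L)
  m <- train_fold(tr, te, config = cfg, fold_id = 2L)
  expect_s3_class(m, "cnn3d")
  expect_identical(nrow(m$history), 2L)
  expect_identical(m$fold_id, 2L)
  # selected epoch maximizes balanced accuracy (ties -> lower loss/earlier)
  h <- m$history
  best <- which(h$test_bacc == max(h$test_bacc))
  if (length(best) > 1L) best <- best[which.min(h$test_loss[best])]
  expect_identical(m$selected_epoch, h$epoch[best[1]])
  # reproducibility
  m2 <- train_fold(tr, te, config = cfg, fold_id = 2L)
  expect_identical(m$history, m2$history)
  expect_identical(m$dense[[2]]$W, m2$dense[[2]]$W)
  expect_error(train_fold(list(volumes = list(), records = tr$records[0, ]), te,
                          config = cfg), "empty")
})

test_that("cross-validation tests every subject exactly once", {
  spec <- small_cohort_spec(seed = 52L, n = c(9L, 5L, 5L), noise_sd = 0.05)
  cohort <- simulate_cohort(spec)
  cfg <- train_config(epochs = 1L, learning_rate = 1e-3, augment = FALSE,
                      seed = 3L)
  cv <- cross_validate(list(volumes = cohort$volumes, records = cohort$records),
                       config = cfg, k = 3L)
  expect_length(cv$models, 3L)
  expect_identical(sort(unique(cv$folds)), 1:3)
  expect_identical(sort(tabulate(cv$folds), decreasing = TRUE), c(7L, 6L, 6L))
  expect_identical(nrow(cv$metrics), 3L)
  expect_true(all(is.finite(cv$metrics$test_auc)))
})

test_that("whole-sample training keeps the final epoch", {
  spec <- small_cohort_spec(seed = 53L, n = c(8L, 4L, 4L))
  cohort <- simulate_cohort(spec)
  cfg <- train_config(epochs = 2L, learning_rate = 1e-3, augment = FALSE,
                      seed = 4L)
  m <- train_full(list(volumes = cohort$volumes, records = cohort$records),
                  config = cfg)
  expect_identical(m$selected_epoch, 2L)
  expect_identical(m$fold_id, "all")
  expect_true(all(is.na(m$history$test_bacc)))
})

test_that("training loss decreases on an easy noiseless task", {
  spec <- cohort_spec(n_control = 10L, n_mci = 0L, n_ad = 10L,
                      grid_shape = c(16L, 16L, 16L), noise_sd = 0,
                      atrophy_regions = list(hippocampus = c(AD = 0.5)),
                      seed = 54L)
  cohort <- simulate_cohort(spec)
  ok <- 0L
  for (s in 1:3) {
    cfg <- train_config(epochs = 3L, learning_rate = 1e-3, augment = FALSE,
                        batch_size = 10L, seed = s)
    m <- train_full(list(volumes = cohort$volumes, records = cohort$records),
                    config = cfg)
    d <- diff(m$history$train_loss)
    if (all(d < 0)) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})

test_that("class-weighted gradients match duplicated minority samples", {
  # weights {2, 1} on a fixed batch equal unit weights with the minority
  # class duplicated twice, up to the normalizing constant
  set.seed(6)
  logits <- matrix(rnorm(8), 2, 4)
  y <- c(0L, 1L, 1L, 1L)
  w <- c(2, 1)
  a <- relmap3d:::weighted_ce(logits, y, w)
  logits_dup <- cbind(logits, logits[, 1])
  y_dup <- c(y, 0L)
  b <- relmap3d:::weighted_ce(logits_dup, y_dup, c(1, 1))
  expect_equal(a$loss, b$loss, tolerance = 1e-12)
  expect_equal(a$dlogits[, 1] , b$dlogits[, 1] + b$dlogits[, 5],
               tolerance = 1e-12)
  expect_lt(max(abs(a$dlogits[, 2:4] - b$dlogits[, 2:4])), 1e-12)
})
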