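test_that("AUC equals the Mann-Whitney pair count", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  for (s in 1:20) {
    set.seed(s)
    n <- sample(6:25, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), brute_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("AUC invariances: monotone transforms and score negation", {
  set.seed(30)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.4)
  a <- roc_auc(sc, lb)
  expect_equal(roc_auc(exp(sc), lb), a, tolerance = 1e-12)
  expect_equal(roc_auc(2 * sc + 5, lb), a, tolerance = 1e-12)
  expect_equal(roc_auc(-sc, lb), 1 - a, tolerance = 1e-12)  # tie-free scores
})

test_that("Youden threshold scans midpoints and ties go to the lowest", {
  r <- youden_threshold(c(0.1, 0.35, 0.4, 0.8), c(0, 1, 0, 1))
  expect_equal(r$youden_j, 0.5)
  expect_equal(r$threshold, 0.225)
  # perfectly separated: J = 1 at the separating midpoint
  r2 <- youden_threshold(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(r2$youden_j, 1)
  expect_equal(r2$threshold, 5)
  expect_equal(r2$balanced_accuracy, 1)
  # J = 2 * balanced accuracy - 1 at the selected threshold
  set.seed(31)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  r3 <- youden_threshold(sc, lb)
  pred <- as.integer(sc >= r3$threshold)
  expect_equal(r3$youden_j, 2 * balanced_accuracy(pred, lb) - 1,
               tolerance = 1e-12)
})

test_that("Youden selection matches an exhaustive scan on random instances", {
  for (s in 1:200) {
    set.seed(s)
    n <- sample(6:30, 1)
    sc <- round(rnorm(n), 2)
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    r <- youden_threshold(sc, lb)
    ref <- brute_youden(sc, lb)
    expect_equal(r$youden_j, unname(ref["j"]), tolerance = 1e-12)
    expect_equal(r$threshold, unname(ref["thr"]), tolerance = 1e-12)
  }
})

test_that("balanced accuracy averages sensitivity and specificity", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # majority-class constant predictor scores 0.5
  expect_equal(balanced_accuracy(rep(1, 10), c(rep(1, 7), rep(0, 3))), 0.5)
  # contingency TP=8 FN=2 TN=6 FP=4 -> (0.8 + 0.6)/2
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 6), rep(1, 4))
  lab <- c(rep(1, 10), rep(0, 10))
  expect_equal(balanced_accuracy(pred, lab), 0.7)
  expect_error(balanced_accuracy(c(1, 0), c(1, 1)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-10)
})

test_that("pearson_r matches the covariance formula and rejects bad input", {
  x <- c(1, 2, 4); y <- c(1, 3, 2)
  ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), ref, tolerance = 1e-12)
  expect_equal(pearson_r(1:10, 2 * (1:10)), 1)
  expect_equal(pearson_r(1:10, -(1:10) + 7), -1)
  expect_error(pearson_r(1:5, rep(1, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("volumetric baseline separates an attenuated cohort and stays at
           chance on a null cohort", {
  gen <- function(atten, seed) {
    spec <- cohort_spec(n_control = 30L, n_mci = 0L, n_ad = 30L,
                        grid_shape = c(20L, 20L, 24L),
                        atrophy_regions = list(hippocampus = c(MCI = atten / 2,
                                                               AD = atten)),
                        noise_sd = 0.1, seed = seed)
    ch <- simulate_cohort(spec)
    hip <- atlas_region_mask(ch$atlas, "hippocampus")
    hv <- vapply(ch$volumes, region_volume_ml, numeric(1), mask = hip)
    y <- as.integer(ch$records$diagnosis != "CN")
    rs <- residualize_scalar(hv, ch$records, ch$records$diagnosis == "CN")
    list(res = rs$residuals, y = y)
  }
  d <- gen(0.4, seed = 61L)
  half <- rep(c(TRUE, FALSE), length.out = length(d$y))
  r <- volumetric_baseline(d$res[half], d$y[half], d$res[!half], d$y[!half])
  expect_gte(r$auc, 0.9)
  expect_true(is.finite(r$volume_threshold_ml))
  # threshold stability: two disjoint halves give similar thresholds
  r2 <- volumetric_baseline(d$res[!half], d$y[!half], d$res[half], d$y[half])
  within_sd <- sd(d$res[d$y == 0])
  expect_lt(abs(r$volume_threshold_ml - r2$volume_threshold_ml), within_sd)
  # null: AUC near chance over replicates
  aucs <- vapply(1:10, function(i) {
    dn <- gen(0, seed = 700L + i)
    roc_auc(-dn$res, dn$y)
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("relevance/volume report: self-correlation and trained-vs-random
           contrast at the reference study conditions", {
  run <- acceptance_runs()[[1]]
  rep_t <- relevance_volume_report(run$model, run$inputs, run$cohort$records,
                                   run$cohort$atlas,
                                   density_volumes = run$cohort$volumes)
  r_tr <- rep_t$table$median_r[rep_t$table$region == "hippocampus"]
  expect_lt(r_tr, -0.5)
  # identical vectors correlate at exactly 1
  rel <- rep_t$relevance[, "hippocampus", 1]
  expect_equal(pearson_r(rel, rel), 1)
  # an untrained model of the same shape shows materially weaker correlation
  untrained <- build_network(run$model$spec, seed = 99)
  rep_u <- relevance_volume_report(untrained, run$inputs, run$cohort$records,
                                   run$cohort$atlas,
                                   density_volumes = run$cohort$volumes)
  r_un <- rep_u$table$median_r[rep_u$table$region == "hippocampus"]
  expect_gt(abs(r_tr) - abs(r_un), 0.2)
})
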