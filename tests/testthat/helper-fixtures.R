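# Shared fixtures and independent brute-force oracles for the test suite.
# Expensive fixtures are built lazily and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

tiny_spec <- function(input = c(8L, 8L, 10L)) {
  network_spec(input_shape = input, n_blocks = 1L, n_filters = 3L,
               dense_units = c(4L, 2L), dropout = 0.1, l2 = 0.01)
}

random_volume <- function(dims = c(12, 12, 14), seed = 1, mean = 0.5, sd = 0.2) {
  set.seed(seed)
  array(rnorm(prod(dims), mean, sd), dims)
}

# a small cohort spec on a 20x20x24 grid; quick to simulate and train
small_cohort_spec <- function(seed = 11L, noise_sd = 0.1, atten = 0.4,
                              n = c(30L, 15L, 15L)) {
  cohort_spec(n_control = n[1], n_mci = n[2], n_ad = n[3],
              grid_shape = c(20L, 20L, 24L),
              atrophy_regions = list(hippocampus = c(MCI = atten / 2, AD = atten),
                                     temporal = c(MCI = atten / 4, AD = atten / 2)),
              noise_sd = noise_sd, seed = seed)
}

# Five independently seeded 200-subject training runs at the package's
# reference synthetic study conditions (40x40x48 grid, hippocampal
# attenuation 0.4, demo training config). Built once and shared between the
# end-to-end acceptance checks and the stochastic property tests; only the
# first run keeps its volumes to bound memory.
acceptance_runs <- function() {
  memo("acceptance_runs", function() {
    lapply(1:5, function(s) {
      spec <- cohort_spec(seed = s)
      cohort <- simulate_cohort(spec)
      ctrl <- cohort$records$diagnosis == "CN"
      rmod <- fit_residualizer(cohort$volumes[ctrl],
                               cohort$records[ctrl, , drop = FALSE])
      inputs <- apply_residualizer(cohort$volumes, cohort$records, rmod)
      folds <- stratified_folds(cohort$records, k = 5L, seed = s)
      test_idx <- folds == 1L
      tr <- list(volumes = inputs[!test_idx],
                 records = cohort$records[!test_idx, , drop = FALSE])
      te <- list(volumes = inputs[test_idx],
                 records = cohort$records[test_idx, , drop = FALSE])
      model <- train_fold(tr, te, config = demo_train_config(seed = s))
      bacc <- max(model$history$test_bacc)
      out <- list(model = model, bacc = bacc, test_idx = test_idx)
      if (s == 1L) {
        out$cohort <- cohort
        out$inputs <- inputs
        out$residual_model <- rmod
      }
      out
    })
  })
}

# ---- oracles --------------------------------------------------------------

# unroll a same-padded 3D convolution into its affine matrix
# (rows = inputs voxel-major then channel, cols = outputs likewise)
unroll_conv <- function(W, dims) {
  kd <- dim(W); Ci <- kd[4]; Co <- kd[5]
  H <- kd[1:3] %/% 2
  S <- prod(dims)
  M <- matrix(0, S * Ci, S * Co)
  lin <- function(i1, i2, i3) i1 + dims[1] * (i2 - 1 + dims[2] * (i3 - 1))
  for (co in seq_len(Co)) for (i3 in seq_len(dims[3])) for (i2 in seq_len(dims[2]))
    for (i1 in seq_len(dims[1])) {
      col <- lin(i1, i2, i3) + S * (co - 1)
      for (ci in seq_len(Ci)) for (k3 in seq_len(kd[3])) for (k2 in seq_len(kd[2]))
        for (k1 in seq_len(kd[1])) {
          j1 <- i1 + k1 - 1 - H[1]; j2 <- i2 + k2 - 1 - H[2]; j3 <- i3 + k3 - 1 - H[3]
          if (j1 >= 1 && j1 <= dims[1] && j2 >= 1 && j2 <= dims[2] &&
              j3 >= 1 && j3 <= dims[3])
            M[lin(j1, j2, j3) + S * (ci - 1), col] <- W[k1, k2, k3, ci, co]
        }
    }
  M
}

# direct evaluation of the alpha1/beta0 redistribution formula on a matrix
brute_alphabeta <- function(W, b, a, R, bias_absorb = FALSE) {
  wp <- pmax(W, 0)
  out <- numeric(nrow(W))
  for (k in seq_len(ncol(W))) {
    zk <- sum(a * wp[, k]) + if (bias_absorb) max(b[k], 0) else 0
    if (zk != 0) out <- out + a * wp[, k] / zk * R[k]
  }
  out
}

brute_epsilon <- function(W, b, a, R, eps = 1e-10, bias_absorb = FALSE) {
  out <- numeric(nrow(W))
  for (k in seq_len(ncol(W))) {
    zk <- sum(a * W[, k]) + if (bias_absorb) b[k] else 0
    out <- out + a * W[, k] / (zk + eps * if (zk >= 0) 1 else -1) * R[k]
  }
  out
}

brute_pool_vals <- function(a, p = 2L) {
  d <- dim(a)
  o <- c(d[1:3] %/% p, d[4])
  out <- array(0, o)
  for (c4 in seq_len(d[4])) for (i3 in seq_len(o[3])) for (i2 in seq_len(o[2]))
    for (i1 in seq_len(o[1]))
      out[i1, i2, i3, c4] <- max(a[((i1 - 1) * p + 1):(i1 * p),
                                   ((i2 - 1) * p + 1):(i2 * p),
                                   ((i3 - 1) * p + 1):(i3 * p), c4])
  out
}

# per-window argmax routing oracle for 2x2x2 pooling
brute_maxpool_route <- function(a, R, p = 2L) {
  d <- dim(a)
  out <- array(0, d)
  o <- d %/% p
  for (i3 in seq_len(o[3])) for (i2 in seq_len(o[2])) for (i1 in seq_len(o[1])) {
    w1 <- ((i1 - 1) * p + 1):(i1 * p)
    w2 <- ((i2 - 1) * p + 1):(i2 * p)
    w3 <- ((i3 - 1) * p + 1):(i3 * p)
    win <- a[w1, w2, w3]
    best <- which.max(win)  # lowest linear index on ties
    bc <- arrayInd(best, dim(win))
    out[w1[bc[1]], w2[bc[2]], w3[bc[3]]] <-
      out[w1[bc[1]], w2[bc[2]], w3[bc[3]]] + R[i1, i2, i3]
  }
  out
}

# union-find connected components oracle
brute_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  idx <- which(mask)
  parent <- seq_along(idx)
  pos <- match(seq_len(prod(d)), idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  offs <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  co <- arrayInd(idx, d)
  for (i in seq_along(idx)) {
    for (r in seq_len(nrow(offs))) {
      nb <- co[i, ] + as.numeric(offs[r, ])
      if (any(nb < 1) || any(nb > d)) next
      j <- pos[nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))]
      if (!is.na(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab <- array(0L, d)
  lab[idx] <- match(roots, unique(roots))
  lab
}

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

brute_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- c(j = -Inf, thr = NA)
  for (thr in cand) {
    sens <- mean(scores[labels == 1] >= thr)
    spec <- mean(scores[labels == 0] < thr)
    j <- sens + spec - 1
    if (j > best["j"]) best <- c(j = j, thr = thr)
  }
  best
}
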