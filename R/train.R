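#' Training configuration
#'
#' The reference settings follow the study conditions of the modelling
#' approach the package implements: adaptive-moment (Adam) optimization,
#' categorical cross-entropy, learning rate 1e-4, batch size 20, and
#' imbalance-correcting class weights `0.5 n / n_i`. Cross-validated training
#' uses 10 epochs on residualized input (20 on raw input); final whole-sample
#' training uses 4 (residualized) or 8 (raw) fixed epochs. The desk-scale
#' synthetic demo overrides `epochs` and `learning_rate` (see
#' [demo_train_config()]).
#'
#' @param epochs number of training epochs (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size minibatch size.
#' @param class_weights optional named per-class loss multipliers; computed
#'   from the training counts when NULL.
#' @param augment use the 14-fold flip/translation augmentation stream.
#' @param shift_voxels translation magnitude of the augmentation.
#' @param seed integer seed for shuffling, dropout and weight init.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, learning_rate = 1e-4, batch_size = 20L,
                         class_weights = NULL, augment = TRUE,
                         shift_voxels = 10L, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights, augment = isTRUE(augment),
                 shift_voxels = as.integer(shift_voxels),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @details `demo_train_config()` is the configuration used for the package's
#'   synthetic demonstrations: 2 epochs at step size 1e-3. The synthetic
#'   separation task is far easier than real MRI cohorts, and with the
#'   14-fold augmentation two epochs already amount to several hundred weight
#'   updates; the larger step size matches the smaller problem.
#' @export
demo_train_config <- function(epochs = 2L, learning_rate = 1e-3, ...) {
  train_config(epochs = epochs, learning_rate = learning_rate, ...)
}

#' Imbalance-correcting class weights
#'
#' `weight_i = 0.5 * n_total / n_i` for each of the two classes, so the
#' minority class is up-weighted in the loss.
#'
#' @param group_counts named numeric vector of per-class training counts
#'   (all > 0).
#' @return named numeric vector of weights.
#' @examples
#' compute_class_weights(c(CN = 254, AD = 409))  # 1.31 / 0.81
#' @export
compute_class_weights <- function(group_counts) {
  if (any(group_counts <= 0))
    stop("all class counts must be positive", call. = FALSE)
  0.5 * sum(group_counts) / group_counts
}

#' Augmentation variants of a volume
#'
#' The full augmented set of one volume: {identity, left/right flip} crossed
#' with {no shift, +/- `shift` voxels along each single axis} — exactly
#' 2 x 7 = 14 variants. Translations vacate voxels which are filled with 0.
#'
#' @param volume 3D array.
#' @param shift translation magnitude in voxels.
#' @param flip_axis axis mirrored by the flip (1 = sagittal L/R).
#' @return list of 14 arrays (variant 1 is the untouched input).
#' @export
augment_variants <- function(volume, shift = 10L, flip_axis = 1L) {
  check_grid3d(volume)
  lapply(seq_len(14L), function(v)
    augment_apply(volume, v, shift = shift, flip_axis = flip_axis))
}

# Variant ids 1..14: (flip in {no, yes}) x (shift in {none, +/-shift per axis}).
augment_apply <- function(volume, variant, shift = 10L, flip_axis = 1L) {
  stopifnot(variant >= 1, variant <= 14)
  v <- as.integer(variant) - 1L
  flip <- v >= 7L
  sh <- v %% 7L  # 0 = none, 1..6 = (+x,-x,+y,-y,+z,-z)
  out <- volume
  if (flip) {
    idx <- rev(seq_len(dim(out)[flip_axis]))
    out <- switch(flip_axis, out[idx, , , drop = FALSE],
                  out[, idx, , drop = FALSE], out[, , idx, drop = FALSE])
  }
  if (sh > 0L) {
    axis <- (sh + 1L) %/% 2L
    t <- if (sh %% 2L == 1L) shift else -shift
    out <- translate3d(out, axis, t)
  }
  out
}

translate3d <- function(x, axis, t) {
  d <- dim(x)
  out <- array(0, d)
  n <- d[axis]
  if (abs(t) >= n) return(out)
  dst <- if (t > 0) (t + 1L):n else 1L:(n + t)
  src <- if (t > 0) 1L:(n - t) else (1L - t):n
  ix <- function(a) if (a == axis) dst else seq_len(d[a])
  sx <- function(a) if (a == axis) src else seq_len(d[a])
  out[ix(1), ix(2), ix(3)] <- x[sx(1), sx(2), sx(3)]
  out
}

#' Stratified k-fold assignment
#'
#' Folds are stratified on the three-class diagnosis (CN/MCI/AD) even though
#' the classifier is binary, so every test partition mirrors the cohort
#' composition; per-stratum fold sizes differ by at most one, and the
#' per-stratum remainders are steered towards the currently smallest folds
#' so that total fold sizes stay balanced too.
#'
#' @param records data.frame with a `diagnosis` column (or a character/factor
#'   vector of diagnoses).
#' @param k number of folds (>= 2, <= smallest stratum size).
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids (1..k) per subject.
#' @export
stratified_folds <- function(records, k = 10L, seed = 1L) {
  diag <- if (is.data.frame(records)) records$diagnosis else as.character(records)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2 (no test partition otherwise)", call. = FALSE)
  tab <- table(diag)
  if (any(tab < k))
    stop(sprintf("k = %d exceeds the smallest stratum size (%d)", k, min(tab)),
         call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  fold <- integer(length(diag))
  totals <- integer(k)
  for (g in names(tab)) {
    idx <- sample(which(diag == g))
    n <- length(idx)
    base <- n %/% k
    extra <- n %% k
    sizes <- rep(base, k)
    if (extra > 0) {
      # give the remainder to the currently smallest folds (random ties)
      ord <- order(totals + stats::runif(k) * 1e-3)
      sizes[ord[seq_len(extra)]] <- base + 1L
    }
    fold[idx] <- rep(seq_len(k), times = sizes)
    totals <- totals + sizes
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  fold
}

binary_labels <- function(diagnosis) as.integer(diagnosis %in% c("MCI", "AD"))

# ---- Adam -----------------------------------------------------------------

adam_init <- function() new.env(parent = emptyenv())

adam_step <- function(state, key, param, grad, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- state[[key]]
  if (is.null(st)) st <- list(m = 0 * grad, v = 0 * grad)
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  state[[key]] <- st
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  param - lr * mhat / (sqrt(vhat) + eps)
}

# Weighted softmax cross-entropy; returns loss and dlogits (classes x n).
weighted_ce <- function(logits, y, weights) {
  p <- softmax_cols(logits)
  n <- ncol(p)
  w <- weights[y + 1L]
  idx <- cbind(y + 1L, seq_len(n))
  eps <- 1e-12
  loss <- -sum(w * log(pmax(p[idx], eps))) / sum(w)
  onehot <- matrix(0, nrow(p), n)
  onehot[idx] <- 1
  dlogits <- sweep(p - onehot, 2, w, "*") / sum(w)
  list(loss = loss, dlogits = dlogits)
}

apply_l2 <- function(net, grads) {
  l2 <- net$spec$l2
  if (l2 <= 0) return(grads)
  nl <- length(net$dense)
  for (l in c(nl - 1L, nl)) {
    if (l >= 1L)
      grads$dense[[l]]$dW <- grads$dense[[l]]$dW + l2 * net$dense[[l]]$W
  }
  grads
}

net_update <- function(net, grads, state, lr, t) {
  for (b in seq_along(net$conv)) {
    g <- grads$conv[[b]]
    net$conv[[b]]$W <- adam_step(state, paste0("cW", b), net$conv[[b]]$W, g$dW, lr, t)
    net$conv[[b]]$b <- adam_step(state, paste0("cb", b), net$conv[[b]]$b, g$db, lr, t)
    if (!is.null(net$conv[[b]]$bn)) {
      net$conv[[b]]$bn$gamma <- adam_step(state, paste0("bg", b),
                                          net$conv[[b]]$bn$gamma, g$dgamma, lr, t)
      net$conv[[b]]$bn$beta <- adam_step(state, paste0("bb", b),
                                         net$conv[[b]]$bn$beta, g$dbeta, lr, t)
    }
  }
  for (l in seq_along(net$dense)) {
    g <- grads$dense[[l]]
    net$dense[[l]]$W <- adam_step(state, paste0("dW", l), net$dense[[l]]$W, g$dW, lr, t)
    net$dense[[l]]$b <- adam_step(state, paste0("db", l), net$dense[[l]]$b, g$db, lr, t)
  }
  net
}

# ---- training loops -------------------------------------------------------

# dataset: list(volumes = list of 3D arrays, records = data.frame with
# diagnosis). Labels are binarized CN (0) vs MCI/AD (1).
dataset_check <- function(dataset) {
  stopifnot(is.list(dataset$volumes), is.data.frame(dataset$records))
  if (length(dataset$volumes) != nrow(dataset$records))
    stop("volumes and records differ in length", call. = FALSE)
  invisible(dataset)
}

#' Train the network on one train/test split
#'
#' Runs the augmented (14x per volume), class-weighted minibatch training
#' stream for the configured number of epochs. After each epoch the test
#' partition is evaluated and the epoch whose weights perform best (balanced
#' accuracy; ties broken by lower test loss, then earlier epoch) is retained
#' — the returned network carries the best epoch's weights, its id in
#' `selected_epoch`, and the per-epoch history.
#'
#' @param train_set,test_set datasets: lists with `volumes` (list of 3D
#'   arrays) and `records` (data.frame with `diagnosis`).
#' @param spec a [network_spec()]; defaults to the spec sized to the data.
#' @param config a [train_config()].
#' @param fold_id identifier stored on the result.
#' @param select_best keep the best-epoch weights (TRUE) or the final-epoch
#'   weights (FALSE, as in whole-sample training).
#' @param verbose print per-epoch metrics.
#' @return A trained `cnn3d`.
#' @export
train_fold <- function(train_set, test_set, spec = NULL, config = train_config(),
                       fold_id = 1L, select_best = TRUE, verbose = FALSE) {
  dataset_check(train_set)
  if (!is.null(test_set)) dataset_check(test_set)
  if (!length(train_set$volumes) || (select_best && !length(test_set$volumes)))
    stop("empty train or test partition", call. = FALSE)
  spec <- spec %||% network_spec(input_shape = dim(train_set$volumes[[1]]))
  ytr <- binary_labels(train_set$records$diagnosis)
  cw <- config$class_weights %||% {
    counts <- c(sum(ytr == 0), sum(ytr == 1))
    names(counts) <- spec$class_labels
    compute_class_weights(counts)
  }
  net <- build_network(spec, seed = config$seed)
  state <- adam_init()
  nvar <- if (config$augment) 14L else 1L
  ntr <- length(train_set$volumes)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed + 1L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     test_loss = numeric(), test_bacc = numeric())
  best <- list(bacc = -Inf, loss = Inf, epoch = NA_integer_, net = NULL)
  t <- 0L
  for (ep in seq_len(config$epochs)) {
    stream <- data.frame(subj = rep(seq_len(ntr), each = nvar),
                         variant = rep(seq_len(nvar), times = ntr))
    stream <- stream[sample(nrow(stream)), ]
    ep_loss <- 0; nbatch <- 0L
    for (start in seq(1L, nrow(stream), by = config$batch_size)) {
      rows <- stream[start:min(start + config$batch_size - 1L, nrow(stream)), ]
      nb <- nrow(rows)
      x <- array(0, c(spec$input_shape, 1L, nb))
      for (j in seq_len(nb))
        x[, , , 1L, j] <- augment_apply(train_set$volumes[[rows$subj[j]]],
                                        rows$variant[j],
                                        shift = config$shift_voxels,
                                        flip_axis = spec$flip_axis)
      y <- ytr[rows$subj]
      masks <- NULL
      if (spec$dropout > 0) {
        din <- c(net$geometry$flatten, spec$dense_units[-length(spec$dense_units)])
        masks <- lapply(din, function(d)
          matrix(rbinom(d * nb, 1, 1 - spec$dropout) / (1 - spec$dropout), d, nb))
      }
      fw <- net_forward(net, x, training = TRUE, dropout_masks = masks,
                        cache = TRUE)
      # harvest the running batch-norm statistics updated this step
      for (b in seq_len(spec$n_blocks))
        if (!is.null(net$conv[[b]]$bn))
          net$conv[[b]]$bn <- fw$caches[[paste0("block", b)]]$bn$bn
      ce <- weighted_ce(fw$logits, y, cw)
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d (lr too high?)",
                     ep, nbatch + 1L), call. = FALSE)
      grads <- apply_l2(net, net_backward(net, fw, ce$dlogits))
      t <- t + 1L
      net <- net_update(net, grads, state, config$learning_rate, t)
      ep_loss <- ep_loss + ce$loss; nbatch <- nbatch + 1L
    }
    ev <- if (!is.null(test_set) && length(test_set$volumes))
      evaluate_on(net, test_set, cw) else list(loss = NA_real_, bacc = NA_real_)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nbatch,
                                   test_loss = ev$loss, test_bacc = ev$bacc))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f, test loss %.4f, test bacc %.3f",
                      ep, ep_loss / nbatch, ev$loss, ev$bacc))
    if (select_best) {
      better <- ev$bacc > best$bacc ||
        (ev$bacc == best$bacc && ev$loss < best$loss)
      if (better) best <- list(bacc = ev$bacc, loss = ev$loss, epoch = ep,
                               net = net)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out <- if (select_best) best$net else net
  out$selected_epoch <- if (select_best) best$epoch else config$epochs
  out$fold_id <- fold_id
  out$history <- hist
  out$config <- config
  out
}

evaluate_on <- function(net, dataset, class_weights, batch = 20L) {
  y <- binary_labels(dataset$records$diagnosis)
  n <- length(dataset$volumes)
  probs <- matrix(NA_real_, 2L, n)
  logits <- matrix(NA_real_, 2L, n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    x <- as_batch(dataset$volumes[idx], net$spec$input_shape)
    fw <- net_forward(net, x, training = FALSE)
    probs[, idx] <- fw$probs
    logits[, idx] <- fw$logits
  }
  ce <- weighted_ce(logits, y, class_weights)
  pred <- as.integer(probs[2L, ] > probs[1L, ])
  bacc <- if (length(unique(y)) == 2L) balanced_accuracy(pred, y) else NA_real_
  list(loss = ce$loss, bacc = bacc, scores = probs[2L, ], labels = y)
}

#' Stratified k-fold cross-validation
#'
#' Composes [stratified_folds()] and [train_fold()]: every subject is tested
#' exactly once, and per-fold metrics (balanced accuracy, AUC at the selected
#' epoch) are collected alongside the models — reported downstream as mean
#' +/- SD across folds.
#'
#' @param dataset list with `volumes` and `records`.
#' @param spec a [network_spec()] (defaults to the data's grid).
#' @param config a [train_config()].
#' @param k number of folds.
#' @param verbose print per-epoch progress.
#' @return list with `models` (list of `cnn3d`), `metrics` (per-fold
#'   data.frame), `folds` (assignment vector).
#' @export
cross_validate <- function(dataset, spec = NULL, config = train_config(),
                           k = 10L, verbose = FALSE) {
  dataset_check(dataset)
  folds <- stratified_folds(dataset$records, k = k, seed = config$seed)
  models <- vector("list", k)
  metrics <- data.frame()
  for (f in seq_len(k)) {
    tr <- list(volumes = dataset$volumes[folds != f],
               records = dataset$records[folds != f, , drop = FALSE])
    te <- list(volumes = dataset$volumes[folds == f],
               records = dataset$records[folds == f, , drop = FALSE])
    cfg <- config
    cfg$seed <- config$seed + f
    m <- train_fold(tr, te, spec = spec, config = cfg, fold_id = f,
                    verbose = verbose)
    ev <- evaluate_on(m, te, compute_class_weights(table(binary_labels(tr$records$diagnosis))))
    auc <- roc_auc(ev$scores, ev$labels)
    metrics <- rbind(metrics, data.frame(fold = f,
                                         selected_epoch = m$selected_epoch,
                                         test_bacc = ev$bacc, test_auc = auc))
    models[[f]] <- m
  }
  list(models = models, metrics = metrics, folds = folds)
}

#' Train on the whole sample with fixed epochs
#'
#' No test partition and no checkpoint selection: the final epoch's weights
#' are returned (`selected_epoch` equals the configured epochs).
#'
#' @inheritParams cross_validate
#' @return A trained `cnn3d` with `fold_id = "all"`.
#' @export
train_full <- function(dataset, spec = NULL, config = train_config(epochs = 4L)) {
  train_fold(dataset, test_set = NULL, spec = spec, config = config,
             fold_id = "all", select_best = FALSE)
}
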