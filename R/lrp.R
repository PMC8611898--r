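#' LRP configuration
#'
#' Composite layer-wise relevance propagation rule: the alpha/beta rule
#' (default alpha = 1, beta = 0 — positive contributions only) on
#' convolutional layers and the epsilon-stabilized rule on dense layers
#' (epsilon = 1e-10). Propagation starts from the pre-softmax score of the
#' target class; dropout is identity at inference; max pooling routes
#' relevance winner-take-all; batch normalization (a per-channel affine at
#' inference that moves no relevance between positions) is identity for
#' propagation, with [fold_batchnorm()] available to absorb it into an
#' adjacent linear layer exactly.
#'
#' @param alpha,beta alpha/beta rule weights; LRP consistency requires
#'   `alpha - beta = 1`.
#' @param epsilon stabilizer of the epsilon rule (> 0).
#' @param conv_rule rule for convolution layers (`"alpha_beta"` or
#'   `"epsilon"`).
#' @param dense_rule rule for dense layers (`"epsilon"` or `"alpha_beta"`).
#' @param input_rule rule for the first (input-facing) convolution. The
#'   alpha/beta rule presumes non-negative activations, which holds for
#'   every inner layer (post-ReLU/pooling) but not for residual images,
#'   whose signed voxel values make the positive-part denominators cancel
#'   arbitrarily close to zero and blow up single-voxel attributions. The
#'   default `"w2"` (squared-weight) rule is the standard input-layer choice
#'   for unbounded real-valued inputs: redistribution coefficients
#'   `w_jk^2 / sum_j w_jk^2` are input-independent, lie in `[0, 1]`, and
#'   conserve relevance exactly.
#' @param bias_absorb if TRUE, biases enter the denominators (the positive/
#'   negative parts for the alpha/beta rule, the full bias for the epsilon
#'   rule) so they absorb a share of the relevance. The default FALSE keeps
#'   every denominator a pure weighted input sum, which conserves relevance
#'   exactly column by column — and on residual images (signed inputs) the
#'   absorbing variant is unstable because near-zero positive parts amplify
#'   the bias share without bound.
#' @return An `lrp_config` list.
#' @export
lrp_config <- function(alpha = 1, beta = 0, epsilon = 1e-10,
                       conv_rule = c("alpha_beta", "epsilon"),
                       dense_rule = c("epsilon", "alpha_beta"),
                       input_rule = c("w2", "alpha_beta", "epsilon"),
                       bias_absorb = FALSE) {
  if (abs(alpha - beta - 1) > 1e-12)
    stop("LRP consistency requires alpha - beta = 1", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 conv_rule = match.arg(conv_rule),
                 dense_rule = match.arg(dense_rule),
                 input_rule = match.arg(input_rule),
                 bias_absorb = isTRUE(bias_absorb),
                 start = "pre-softmax score of target class"),
            class = "lrp_config")
}

sign0 <- function(z) ifelse(z >= 0, 1, -1)  # sign(0) := +1 by convention

#' Alpha/beta relevance propagation through an affine layer
#'
#' Implements `R_j = sum_k [ alpha a_j w+_jk / z+_k  -  beta a_j w-_jk / z-_k ] R_k`
#' with `z+_k = sum_j a_j w+_jk` (plus `max(b_k, 0)` when `bias_absorb` is
#' TRUE, in which case the bias absorbs part of the relevance) and the
#' mirrored negative part. Biases never appear in the numerator. Columns
#' with a zero denominator drop their relevance rather than redistributing
#' it.
#'
#' @param W weight matrix, inputs x outputs (a convolution can be passed in
#'   its unrolled affine form).
#' @param b bias vector (length = outputs).
#' @param activations the layer's true forward inputs `a_j`.
#' @param relevance relevance `R_k` attributed to the layer outputs.
#' @param alpha,beta rule weights (`alpha - beta = 1`).
#' @param bias_absorb include the positive/negative bias parts in the
#'   denominators (see [lrp_config()]).
#' @return relevance vector over the inputs.
#' @examples
#' propagate_alphabeta(matrix(c(0.5, 0.5), 2, 1), 0, c(1, 2), 1)  # 1/3, 2/3
#' @export
propagate_alphabeta <- function(W, b, activations, relevance,
                                alpha = 1, beta = 0, bias_absorb = FALSE) {
  W <- as.matrix(W)
  stopifnot(length(activations) == nrow(W), length(relevance) == ncol(W))
  wp <- pmax(W, 0); wn <- pmin(W, 0)
  zp <- drop(crossprod(wp, activations)) + if (bias_absorb) pmax(b, 0) else 0
  sp <- ifelse(zp == 0, 0, relevance / zp)
  out <- alpha * activations * drop(wp %*% sp)
  if (beta != 0) {
    zn <- drop(crossprod(wn, activations)) + if (bias_absorb) pmin(b, 0) else 0
    sn <- ifelse(zn == 0, 0, relevance / zn)
    out <- out - beta * activations * drop(wn %*% sn)
  }
  out
}

#' Epsilon-rule relevance propagation through an affine layer
#'
#' `R_j = sum_k a_j w_jk / (z_k + epsilon * sign(z_k)) R_k` with
#' `z_k = sum_j a_j w_jk` the weighted input sum — the small constant extends
#' the same denominator the alpha/beta redistribution normalizes by — and
#' `sign(0) := +1`. The stabilizer absorbs relevance where the activation of
#' neuron `k` is weak or contradictory; apart from that absorption the rule
#' conserves relevance exactly. With `bias_absorb = TRUE` the bias joins the
#' denominator (the full pre-activation), so biases additionally soak up a
#' `b_k / z_k` share.
#'
#' @inheritParams propagate_alphabeta
#' @param epsilon stabilizer (> 0).
#' @return relevance vector over the inputs.
#' @export
propagate_epsilon <- function(W, b, activations, relevance, epsilon = 1e-10,
                              bias_absorb = FALSE) {
  W <- as.matrix(W)
  stopifnot(length(activations) == nrow(W), length(relevance) == ncol(W))
  z <- drop(crossprod(W, activations)) + if (bias_absorb) b else 0
  s <- relevance / (z + epsilon * sign0(z))
  activations * drop(W %*% s)
}

#' Winner-take-all relevance routing through max pooling
#'
#' Each pooling window's relevance goes entirely to the window's maximal
#' input; ties resolve to the lowest linear index. Conserves relevance
#' exactly.
#'
#' @param input_activations the layer's forward input, a 3D array or
#'   (d1,d2,d3,C) array.
#' @param relevance relevance on the pooled grid (matching pooled dims).
#' @param pool pooling window edge.
#' @return relevance array shaped like `input_activations`.
#' @export
propagate_maxpool <- function(input_activations, relevance, pool = 2L) {
  d <- dim(input_activations)
  if (length(d) == 3L) d <- c(d, 1L)
  x <- array(input_activations, c(d, 1L))
  pl <- maxpool3d_fwd_cpp(x, as.integer(pool))
  dr <- dim(relevance)
  if (length(dr) == 3L) dr <- c(dr, 1L)
  if (!identical(as.integer(dr), dim(pl$y)[1:4]))
    stop("relevance shape does not match the pooled grid", call. = FALSE)
  out <- maxpool3d_bwd_cpp(array(relevance, c(dr, 1L)), pl$argmax, d[1:3])
  array(out, dim(input_activations))
}

#' Fold batch normalization into an adjacent linear layer
#'
#' At inference batch normalization is the per-channel affine map
#' `u = s * x + t` with `s = gamma / sqrt(var + eps)` and
#' `t = beta - gamma * mean / sqrt(var + eps)`. Because the neighboring
#' convolution/dense layer is linear, the affine map folds into its weights
#' and bias exactly; relevance propagation then never sees the
#' normalization layer.
#'
#' @param W,b the linear layer's weights and bias (conv kernel
#'   `(k1,k2,k3,Cin,Cout)` or dense matrix inputs x outputs).
#' @param bn batch-norm parameter list (`gamma`, `beta`, `rmean`, `rvar`,
#'   `eps`).
#' @param where `"after_conv"` (BN consumes the conv output),
#'   `"before_conv"` (BN feeds the conv input channels) or `"before_dense"`
#'   (BN feeds the dense layer through the flatten map). The after-conv and
#'   before-dense folds are exact everywhere; the before-conv fold absorbs
#'   the shift into a constant output bias, which is exact for interior
#'   voxels but slightly off at zero-padded borders, where kernel taps fall
#'   outside the grid and contribute no shift.
#' @param spatial for `"before_dense"`: number of voxels per channel in the
#'   flatten ordering.
#' @return list with folded `W`, `b`, and `bn` marked `folded = TRUE`.
#' @export
fold_batchnorm <- function(W, b, bn, where = c("after_conv", "before_conv",
                                               "before_dense"),
                           spatial = NULL) {
  where <- match.arg(where)
  istd <- 1 / sqrt(bn$rvar + bn$eps)
  s <- bn$gamma * istd
  t <- bn$beta - bn$gamma * bn$rmean * istd
  if (where == "after_conv") {
    d <- dim(W); Co <- d[5]
    Wf <- W
    for (co in seq_len(Co)) Wf[, , , , co] <- W[, , , , co] * s[co]
    bf <- s * b + t
  } else if (where == "before_conv") {
    d <- dim(W); Ci <- d[4]; Co <- d[5]
    Wf <- W
    for (ci in seq_len(Ci)) Wf[, , , ci, ] <- W[, , , ci, ] * s[ci]
    bf <- b + vapply(seq_len(Co), function(co)
      sum(sweep(array(W[, , , , co], d[1:4]), 4, t, "*")), numeric(1))
  } else {
    if (is.null(spatial)) stop("spatial required for before_dense", call. = FALSE)
    ch <- rep(seq_along(s), each = spatial)
    if (length(ch) != nrow(W))
      stop("spatial x channels does not match the dense input width", call. = FALSE)
    Wf <- W * s[ch]
    bf <- b + drop(crossprod(W, t[ch]))
  }
  bn$folded <- TRUE
  list(W = Wf, b = bf, bn = bn)
}

#' Relevance propagation through a (folded) batch-norm layer
#'
#' After [fold_batchnorm()] the normalization has been absorbed by the
#' neighboring linear layer, so propagation through the fold itself is the
#' identity. Calling this on an unfolded layer is an error: propagating
#' through a free-standing normalization is not part of the composite rule.
#'
#' @param bn batch-norm parameter list (must carry `folded = TRUE`).
#' @param input_activations forward inputs (unused; interface symmetry).
#' @param relevance incoming relevance.
#' @return `relevance`, unchanged.
#' @export
propagate_batchnorm <- function(bn, input_activations, relevance) {
  if (!isTRUE(bn$folded))
    stop("batch-norm must be folded into an adjacent linear layer before propagation",
         call. = FALSE)
  relevance
}

# Alpha/beta propagation through a conv layer using the conv kernels
# (same computation as the unrolled-matrix form, without materializing it).
conv_alphabeta <- function(W, b, a, R, alpha = 1, beta = 0,
                           bias_absorb = FALSE) {
  Ci <- dim(W)[4]
  Co <- dim(W)[5]
  wp <- pmax(W, 0); attr(wp, "dim") <- dim(W)
  zp <- conv3d_fwd_cpp(a, wp, if (bias_absorb) pmax(b, 0) else numeric(Co))
  s <- array(0, dim(zp)); nz <- zp != 0
  s[nz] <- R[nz] / zp[nz]
  out <- alpha * a * conv3d_bwd_data_cpp(s, wp, Ci)
  if (beta != 0) {
    wn <- pmin(W, 0); attr(wn, "dim") <- dim(W)
    zn <- conv3d_fwd_cpp(a, wn, if (bias_absorb) pmin(b, 0) else numeric(Co))
    sn <- array(0, dim(zn)); nzn <- zn != 0
    sn[nzn] <- R[nzn] / zn[nzn]
    out <- out - beta * a * conv3d_bwd_data_cpp(sn, wn, Ci)
  }
  out
}

conv_epsilon <- function(W, b, a, R, epsilon, bias_absorb = FALSE) {
  Ci <- dim(W)[4]
  Co <- dim(W)[5]
  z <- conv3d_fwd_cpp(a, W, if (bias_absorb) b else numeric(Co))
  s <- R / (z + epsilon * sign0(z))
  a * conv3d_bwd_data_cpp(s, W, Ci)
}

# squared-weight redistribution: coefficients w^2 / sum(w^2), independent of
# the activations; the input-layer rule for unbounded real-valued inputs
conv_w2 <- function(W, a, R) {
  Ci <- dim(W)[4]
  Co <- dim(W)[5]
  w2 <- W * W; attr(w2, "dim") <- dim(W)
  ones <- array(1, dim(a))
  z <- conv3d_fwd_cpp(ones, w2, numeric(Co))  # per-column sum of valid w^2
  s <- array(0, dim(z)); nz <- z != 0
  s[nz] <- R[nz] / z[nz]
  conv3d_bwd_data_cpp(s, w2, Ci)
}

#' Compute a voxel relevance map for one volume
#'
#' Back-propagates the pre-softmax score of the target class through the
#' network: epsilon rule on dense layers, alpha/beta rule on convolutions,
#' winner-take-all through max pooling, identity through dropout and through
#' the per-channel batch-norm affine (which moves no relevance between
#' positions), ReLU handled implicitly through the cached forward
#' activations. Per-layer relevance totals are recorded as a conservation
#' diagnostic; the end-to-end deficit is bounded by the layers' bias shares.
#'
#' @param network a trained (or at least built) `cnn3d`.
#' @param volume input volume matching the network's input shape.
#' @param target_class class name or index whose evidence is mapped
#'   (default: the disease class, i.e. the second class label).
#' @param config an [lrp_config()].
#' @return A `relevance_map`: `values` (3D array aligned to the input),
#'   `target_class`, `start_relevance` (the class's pre-softmax score) and
#'   `layer_totals`.
#' @export
relevance_map <- function(network, volume, target_class = NULL,
                          config = lrp_config()) {
  sp <- network$spec
  labels <- sp$class_labels
  target_class <- target_class %||% labels[length(labels)]
  tc <- if (is.numeric(target_class)) as.integer(target_class)
        else match(target_class, labels)
  if (is.na(tc) || tc < 1L || tc > length(labels))
    stop("invalid target class: ", target_class, call. = FALSE)
  x <- as_batch(volume, sp$input_shape)
  stopifnot(dim(x)[5] == 1L)
  fw <- net_forward(network, x, training = FALSE, cache = TRUE)
  caches <- fw$caches
  nl <- length(network$dense)
  nb <- sp$n_blocks
  start <- fw$logits[tc, 1L]
  totals <- c(start = start)

  dense_rule <- function(W, b, a, R) {
    if (config$dense_rule == "epsilon")
      propagate_epsilon(W, b, a, R, config$epsilon, config$bias_absorb)
    else propagate_alphabeta(W, b, a, R, config$alpha, config$beta,
                             config$bias_absorb)
  }

  # dense stack, top down; each rule sees the layer's true forward inputs
  R <- numeric(length(labels)); R[tc] <- start
  for (l in rev(seq_len(nl))) {
    dl <- network$dense[[l]]
    a <- caches$dense[[l]][, 1L]
    R <- dense_rule(dl$W, dl$b, a, R)
    totals[paste0("dense", l)] <- sum(R)
  }

  # conv stack, top down. The batch normalization feeding each inner
  # convolution is folded into that convolution exactly (it is a per-channel
  # affine and the convolution is linear), so the alpha/beta rule always
  # sees the non-negative pooled activations as its inputs — with alpha = 1,
  # beta = 0 every redistribution coefficient then lies in [0, 1] and the
  # propagation cannot amplify relevance. The normalization above the dense
  # stack is identity for propagation (it moves no relevance between
  # positions). Only the input layer receives signed (residual) activations.
  Rarr <- array(R, c(network$geometry$post_pool[[nb]], sp$n_filters, 1L))
  for (b in rev(seq_len(nb))) {
    cc <- caches[[paste0("block", b)]]
    # pool: winner-take-all back to the conv/ReLU grid
    Rarr <- maxpool3d_bwd_cpp(Rarr, cc$argmax, dim(cc$r)[1:3])
    totals[paste0("pool", b)] <- sum(Rarr)
    cb <- network$conv[[b]]
    if (b > 1L && sp$batch_norm) {
      fold <- fold_batchnorm(cb$W, cb$b, network$conv[[b - 1L]]$bn,
                             where = "before_conv")
      W <- fold$W; bb <- fold$b
      a <- caches[[paste0("block", b - 1L)]]$pool
    } else {
      W <- cb$W; bb <- cb$b
      a <- if (b > 1L) caches[[paste0("block", b - 1L)]]$out else caches$x
    }
    rule <- if (b == 1L) config$input_rule else config$conv_rule
    Rarr <- switch(rule,
                   alpha_beta = conv_alphabeta(W, bb, a, Rarr, config$alpha,
                                               config$beta, config$bias_absorb),
                   epsilon = conv_epsilon(W, bb, a, Rarr, config$epsilon,
                                          config$bias_absorb),
                   w2 = conv_w2(W, a, Rarr))
    totals[paste0("conv", b)] <- sum(Rarr)
  }
  structure(list(values = array(Rarr, sp$input_shape),
                 target_class = labels[tc], start_relevance = start,
                 layer_totals = totals, config = config,
                 voxel_size_mm = voxel_size(volume)),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("relevance_map %s for class %s; start %.4g, map total %.4g (deficit %.3g%%)\n",
              paste(dim(x$values), collapse = "x"), x$target_class,
              x$start_relevance, sum(x$values),
              100 * abs(sum(x$values) - x$start_relevance) /
                max(abs(x$start_relevance), .Machine$double.eps)))
  invisible(x)
}

#' @export
plot.relevance_map <- function(x, slice = NULL, axis = 3L, ...) {
  d <- dim(x$values)
  slice <- slice %||% ((d[axis] + 1L) %/% 2L)
  sl <- switch(axis, x$values[slice, , ], x$values[, slice, ],
               x$values[, , slice])
  graphics::image(sl, main = sprintf("relevance (%s), slice %d axis %d",
                                     x$target_class, slice, axis),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Write a relevance map as NIfTI plus a JSON diagnostics sidecar
#'
#' @param map a `relevance_map`.
#' @param path output `.nii.gz` path.
#' @export
write_relevance_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- rep(map$voxel_size_mm, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(list(target_class = map$target_class,
                            start_relevance = map$start_relevance,
                            start_definition = map$config$start,
                            layer_totals = as.list(map$layer_totals)),
                       sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
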