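#' Network architecture specification
#'
#' Describes the 3D CNN used throughout the package: three convolution
#' blocks (5 filters of 3x3x3, spatial-size-preserving padding, ReLU,
#' 2x2x2 max pooling with floor division, batch normalization), followed by
#' three dense layers of 64, 32 and 2 units, each preceded by 10% dropout,
#' with ReLU activations and a softmax output. The weights of the last two
#' dense layers carry an L2 penalty. At the full 100x100x120 resolution this
#' architecture has ~700,000 trainable parameters.
#'
#' @param input_shape 3 positive integers; every dimension must survive
#'   `n_blocks` halvings (>= `pool^n_blocks`).
#' @param n_filters convolution filters per block.
#' @param kernel 3D kernel size (odd).
#' @param n_blocks number of conv/pool blocks.
#' @param pool pooling window edge (floor-divides the spatial dims).
#' @param batch_norm include batch normalization after each pooling step.
#' @param dense_units dense layer widths; the last entry is the class count.
#' @param dropout dropout rate applied before each dense layer (training
#'   only).
#' @param l2 L2 penalty strength on the last two dense layers' weights.
#' @param flip_axis grid axis mirrored by the left/right augmentation flip
#'   (axis 1 = sagittal under the package's x/y/z = sagittal/coronal/axial
#'   convention).
#' @param class_labels class names, negative class first.
#' @return A `network_spec` list.
#' @export
network_spec <- function(input_shape = c(40L, 40L, 48L), n_filters = 5L,
                         kernel = c(3L, 3L, 3L), n_blocks = 3L, pool = 2L,
                         batch_norm = TRUE, dense_units = c(64L, 32L, 2L),
                         dropout = 0.1, l2 = 0.01, flip_axis = 1L,
                         class_labels = c("CN", "AD")) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L)
  if (any(input_shape <= 0)) stop("input dimensions must be positive", call. = FALSE)
  if (any(input_shape < pool^n_blocks))
    stop(sprintf("input %s too small: every dimension must be >= %d to survive %d poolings",
                 paste(input_shape, collapse = "x"), pool^n_blocks, n_blocks),
         call. = FALSE)
  if (any(kernel %% 2L == 0L)) stop("kernel dims must be odd", call. = FALSE)
  if (utils::tail(dense_units, 1) != length(class_labels))
    stop("last dense layer width must equal the number of classes", call. = FALSE)
  structure(list(input_shape = input_shape, n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel), n_blocks = as.integer(n_blocks),
                 pool = as.integer(pool), batch_norm = isTRUE(batch_norm),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 l2 = l2, flip_axis = as.integer(flip_axis),
                 class_labels = class_labels),
            class = "network_spec")
}

# Spatial dims after each pooling step (floor division), and the flatten width.
spec_geometry <- function(spec) {
  dims <- list(spec$input_shape)
  d <- spec$input_shape
  for (b in seq_len(spec$n_blocks)) {
    d <- d %/% spec$pool
    dims[[b + 1]] <- d
  }
  list(post_pool = dims[-1],
       flatten = as.integer(prod(dims[[spec$n_blocks + 1]]) * spec$n_filters))
}

#' Build a randomly initialized network
#'
#' Weights use normalized-variance uniform (Glorot) initialization, biases
#' start at zero, batch-norm at scale 1 / shift 0 with unit running variance.
#' Two builds with the same seed are identical.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight draw.
#' @return A `cnn3d` object (untrained).
#' @examples
#' net <- build_network(network_spec(c(16, 16, 16)), seed = 1)
#' count_parameters(net)
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  glorot <- function(dims, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    array(runif(prod(dims), -lim, lim), dims)
  }
  conv <- list()
  cin <- 1L
  for (b in seq_len(spec$n_blocks)) {
    kd <- c(spec$kernel, cin, spec$n_filters)
    conv[[b]] <- list(
      W = glorot(kd, prod(spec$kernel) * cin, prod(spec$kernel) * spec$n_filters),
      b = numeric(spec$n_filters),
      bn = if (spec$batch_norm) list(gamma = rep(1, spec$n_filters),
                                     beta = numeric(spec$n_filters),
                                     rmean = numeric(spec$n_filters),
                                     rvar = rep(1, spec$n_filters),
                                     eps = 1e-3, momentum = 0.9))
    cin <- spec$n_filters
  }
  geo <- spec_geometry(spec)
  dense <- list()
  din <- geo$flatten
  for (l in seq_along(spec$dense_units)) {
    dout <- spec$dense_units[l]
    dense[[l]] <- list(W = glorot(c(din, dout), din, dout), b = numeric(dout))
    din <- dout
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(spec = spec, conv = conv, dense = dense, geometry = geo,
                 selected_epoch = NA_integer_, fold_id = NA, history = NULL,
                 config = NULL),
            class = "cnn3d")
}

#' Count trainable parameters
#'
#' Sums conv kernels and biases, batch-norm scale/shift, and dense weights
#' and biases (running statistics are not trainable).
#'
#' @param network a `cnn3d`.
#' @return integer parameter count.
#' @export
count_parameters <- function(network) {
  n <- 0L
  for (cb in network$conv) {
    n <- n + length(cb$W) + length(cb$b)
    if (!is.null(cb$bn)) n <- n + length(cb$bn$gamma) + length(cb$bn$beta)
  }
  for (dl in network$dense) n <- n + length(dl$W) + length(dl$b)
  as.integer(n)
}

#' @export
print.cnn3d <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("cnn3d: input %s, %d conv block(s) x %d filters, dense %s\n",
              paste(sp$input_shape, collapse = "x"), sp$n_blocks, sp$n_filters,
              paste(sp$dense_units, collapse = "/")))
  cat(sprintf("  %s parameters; %s\n",
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$history)) "untrained"
              else sprintf("trained (fold %s, selected epoch %s)",
                           x$fold_id, x$selected_epoch)))
  invisible(x)
}

#' @export
summary.cnn3d <- function(object, ...) {
  print(object)
  geo <- object$geometry
  d <- object$spec$input_shape
  for (b in seq_len(object$spec$n_blocks)) {
    pp <- geo$post_pool[[b]]
    cat(sprintf("  block %d: conv %s -> pool %s (x%d ch)%s\n", b,
                paste(d, collapse = "x"), paste(pp, collapse = "x"),
                object$spec$n_filters,
                if (object$spec$batch_norm) " -> batch-norm" else ""))
    d <- pp
  }
  cat(sprintf("  flatten: %d\n", geo$flatten))
  if (!is.null(object$history)) {
    cat("  per-epoch test metrics:\n")
    print(object$history)
  }
  invisible(object)
}

# ---- forward / backward ---------------------------------------------------

as_batch <- function(volumes, input_shape) {
  if (is.list(volumes)) {
    n <- length(volumes)
    x <- array(0, c(input_shape, 1L, n))
    for (j in seq_len(n)) {
      check_same_shape(volumes[[j]], array(0, input_shape),
                       c("volume", "network input"))
      x[, , , 1L, j] <- volumes[[j]]
    }
    return(x)
  }
  d <- dim(volumes)
  if (length(d) == 3L) {
    if (!identical(as.integer(d), as.integer(input_shape)))
      stop(sprintf("volume shape (%s) does not match network input (%s)",
                   paste(d, collapse = "x"), paste(input_shape, collapse = "x")),
           call. = FALSE)
    return(array(volumes, c(d, 1L, 1L)))
  }
  if (length(d) == 5L) return(volumes)
  if (length(d) == 4L) return(array(volumes, c(d[1:3], 1L, d[4])))
  stop("cannot interpret network input of dim ", paste(d, collapse = "x"),
       call. = FALSE)
}

bn_affine <- function(bn) {
  istd <- 1 / sqrt(bn$rvar + bn$eps)
  list(scale = bn$gamma * istd, shift = bn$beta - bn$gamma * bn$rmean * istd)
}

# Forward pass. training = TRUE uses batch statistics (and updates running
# ones by reference convention: returns updated bn in the cache), dropout
# masks must then be supplied. cache = TRUE retains per-layer activations.
net_forward <- function(net, x, training = FALSE, dropout_masks = NULL,
                        cache = FALSE) {
  sp <- net$spec
  caches <- list(x = if (cache) x)
  a <- x
  for (b in seq_len(sp$n_blocks)) {
    cb <- net$conv[[b]]
    r <- relu_inplace_cpp(conv3d_fwd_cpp(a, cb$W, cb$b))
    pl <- maxpool3d_fwd_cpp(r, sp$pool)
    u <- pl$y
    bncache <- NULL
    if (!is.null(cb$bn)) {
      if (training) {
        bnf <- bn_forward_train(u, cb$bn)
        u <- bnf$y
        bncache <- bnf
      } else {
        af <- bn_affine(cb$bn)
        u <- bn_apply_cpp(u, af$scale, af$shift)
      }
    }
    if (cache)
      caches[[paste0("block", b)]] <- list(r = r, argmax = pl$argmax,
                                           pool = pl$y, bn = bncache, out = u)
    a <- u
  }
  d <- dim(a)
  f <- matrix(a, prod(d[1:4]), d[5])  # flatten: features x samples
  acts <- list()
  nl <- length(net$dense)
  for (l in seq_len(nl)) {
    if (training && sp$dropout > 0) {
      f <- f * dropout_masks[[l]]
    }
    if (cache) acts[[l]] <- f
    dl <- net$dense[[l]]
    zl <- crossprod(dl$W, f) + dl$b
    if (l < nl) { fnext <- zl; fnext[fnext < 0] <- 0 } else fnext <- zl
    if (cache) acts[[paste0("z", l)]] <- zl
    f <- fnext
  }
  logits <- f  # classes x samples
  probs <- softmax_cols(logits)
  list(logits = logits, probs = probs,
       caches = if (cache) c(caches, list(dense = acts,
                                          dropout = dropout_masks)))
}

softmax_cols <- function(z) {
  zm <- sweep(z, 2, apply(z, 2, max))
  e <- exp(zm)
  sweep(e, 2, colSums(e), "/")
}

bn_forward_train <- function(x, bn) {
  st <- bn_stats_cpp(x)
  istd <- 1 / sqrt(st$var + bn$eps)
  y <- bn_apply_cpp(x, bn$gamma * istd, bn$beta - bn$gamma * st$mean * istd)
  bn$rmean <- bn$momentum * bn$rmean + (1 - bn$momentum) * st$mean
  bn$rvar <- bn$momentum * bn$rvar + (1 - bn$momentum) * st$var
  list(y = y, mean = st$mean, istd = istd, bn = bn)
}

bn_backward <- function(dy, x, bnf, gamma) {
  bn_bwd_cpp(dy, x, bnf$mean, bnf$istd, gamma)
}

# Backward pass for one batch. Returns gradients in the same nesting as the
# network parameters. dlogits: classes x samples.
net_backward <- function(net, fw, dlogits) {
  sp <- net$spec
  caches <- fw$caches
  nl <- length(net$dense)
  grads <- list(conv = vector("list", sp$n_blocks),
                dense = vector("list", nl))
  # dcur holds the gradient wrt layer l's pre-activation z_l
  dcur <- dlogits
  for (l in rev(seq_len(nl))) {
    a <- caches$dense[[l]]          # post-dropout input of layer l
    dW <- a %*% t(dcur)
    db <- rowSums(dcur)
    dinp <- net$dense[[l]]$W %*% dcur
    if (!is.null(caches$dropout)) dinp <- dinp * caches$dropout[[l]]
    grads$dense[[l]] <- list(dW = dW, db = db)
    if (l > 1L) {
      zprev <- caches$dense[[paste0("z", l - 1L)]]
      dcur <- dinp * (zprev > 0)
    } else dcur <- dinp
  }
  # reshape flatten gradient to the last block's output
  lastd <- c(net$geometry$post_pool[[sp$n_blocks]], sp$n_filters,
             ncol(dlogits))
  dblock <- array(dcur, lastd)
  for (b in rev(seq_len(sp$n_blocks))) {
    cb <- net$conv[[b]]
    cc <- caches[[paste0("block", b)]]
    if (!is.null(cb$bn)) {
      bnb <- bn_backward(dblock, cc$pool, cc$bn, cb$bn$gamma)
      grads$conv[[b]]$dgamma <- bnb$dgamma
      grads$conv[[b]]$dbeta <- bnb$dbeta
      dblock <- bnb$dx
    }
    dz <- maxpool3d_bwd_relu_cpp(dblock, cc$argmax, cc$r)
    xin <- if (b == 1L) caches$x else caches[[paste0("block", b - 1L)]]$out
    wb <- conv3d_bwd_wb_cpp(xin, dz, dim(cb$W)[1:3])
    grads$conv[[b]]$dW <- wb$dw
    grads$conv[[b]]$db <- wb$db
    if (b > 1L) dblock <- conv3d_bwd_data_cpp(dz, cb$W, dim(cb$W)[4])
  }
  grads
}

#' Predict class probabilities for volumes
#'
#' Runs the network in inference mode (dropout off, frozen batch-norm
#' statistics). Softmax probabilities are non-negative and sum to one;
#' pre-softmax scores are available via `type = "logit"` (the relevance
#' engine starts from these).
#'
#' @param object a `cnn3d`.
#' @param newdata a 3D volume, list of volumes, or 4D/5D array.
#' @param type `"prob"` (default), `"logit"`, or `"class"`.
#' @param ... unused.
#' @return For a single volume a named vector over classes (or a class
#'   label); otherwise a samples x classes matrix (or label vector).
#' @export
predict.cnn3d <- function(object, newdata, type = c("prob", "logit", "class"),
                          ...) {
  type <- match.arg(type)
  x <- as_batch(newdata, object$spec$input_shape)
  fw <- net_forward(object, x, training = FALSE, cache = FALSE)
  out <- switch(type, prob = fw$probs, logit = fw$logits,
                class = fw$probs)
  labels <- object$spec$class_labels
  if (type == "class") {
    idx <- apply(out, 2, which.max)
    cls <- labels[idx]
    return(if (ncol(out) == 1L) cls[1] else cls)
  }
  m <- t(out)
  colnames(m) <- labels
  if (nrow(m) == 1L) drop(m) else m
}
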