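#' Architecture specification for the 1-D convolutional classifier
#'
#' The classifier is a stack of identical blocks, each
#' 1-D convolution (ELU activation, L2 penalty on weights and biases) ->
#' group normalization -> max pooling -> dropout, followed by flatten ->
#' dense (ELU, L2) -> dense(1, sigmoid). Defaults are the tuned values:
#' two blocks of 32 filters, kernel 5, stride 1, 4 normalization groups,
#' pooling 4 with stride 2, dropout 0.25, 32 dense units and L2 weight 1e-4.
#' Convolutions and pooling use "same" padding, so a block maps P positions
#' to ceiling(P / pool_stride).
#'
#' @param n_blocks Number of conv blocks.
#' @param filters Convolution filters per block; must be divisible by
#'   `groups`.
#' @param kernel_size Convolution kernel width.
#' @param conv_stride Convolution stride (only 1 is supported, as used here).
#' @param groups Group-normalization group count.
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @param dropout Dropout probability in \[0, 1).
#' @param dense_units Units in the penultimate dense layer.
#' @param l2_weight L2 penalty applied to the weights *and* biases of every
#'   convolution and of the first dense layer.
#' @return An object of class `fourmc_cnn_spec`.
#' @export
cnn_spec <- function(n_blocks = 2L, filters = 32L, kernel_size = 5L,
                     conv_stride = 1L, groups = 4L, pool_size = 4L,
                     pool_stride = 2L, dropout = 0.25, dense_units = 32L,
                     l2_weight = 1e-4) {
  counts <- c(n_blocks = n_blocks, filters = filters,
              kernel_size = kernel_size, conv_stride = conv_stride,
              groups = groups, pool_size = pool_size,
              pool_stride = pool_stride, dense_units = dense_units)
  if (any(counts < 1)) {
    abort(paste0("all architecture counts must be positive; got ",
                 paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (conv_stride != 1L) {
    abort("only conv_stride = 1 is supported")
  }
  if (filters %% groups != 0) {
    abort(paste0("filters (", filters, ") must be divisible by the number ",
                 "of normalization groups (", groups, ")"))
  }
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must be in [0, 1)")
  }
  if (l2_weight < 0) {
    abort("`l2_weight` must be non-negative")
  }
  structure(
    list(n_blocks = as.integer(n_blocks), filters = as.integer(filters),
         kernel_size = as.integer(kernel_size),
         conv_stride = as.integer(conv_stride), groups = as.integer(groups),
         pool_size = as.integer(pool_size),
         pool_stride = as.integer(pool_stride), dropout = dropout,
         dense_units = as.integer(dense_units), l2_weight = l2_weight),
    class = "fourmc_cnn_spec"
  )
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum 0.95 and learning rate 0.005,
#' binary cross-entropy loss, 100 epochs of batch size 32, early stopping on
#' validation loss with patience 30, restoring the best-epoch weights
#' (checkpointing).
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); must not exceed `epochs`.
#' @param checkpoint_best Restore the best-validation-epoch weights after
#'   training (default `TRUE`); otherwise the final epoch's weights are kept.
#' @param seed Integer seed controlling weight initialization, shuffling and
#'   dropout.
#' @return An object of class `fourmc_train_config`.
#' @export
train_config <- function(learning_rate = 0.005, momentum = 0.95,
                         epochs = 100L, batch_size = 32L, patience = 30L,
                         checkpoint_best = TRUE, seed = 1L) {
  if (any(c(learning_rate, epochs, batch_size, patience) <= 0)) {
    abort("learning_rate, epochs, batch_size and patience must be positive")
  }
  if (patience > epochs) {
    abort("`patience` must not exceed `epochs`")
  }
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         patience = as.integer(patience),
         checkpoint_best = isTRUE(checkpoint_best), seed = as.integer(seed)),
    class = "fourmc_train_config"
  )
}

# Position counts after each block's pooling stage, and the flatten width.
chain_shapes <- function(spec, input_shape) {
  P <- input_shape[1]
  positions <- integer(spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    if (P < spec$kernel_size) {
      abort(paste0(
        "input too short for the conv/pool chain: block ", b, " sees ", P,
        " positions but the kernel is ", spec$kernel_size, " wide"
      ))
    }
    P <- pool_out_len(P, spec$pool_stride)
    positions[b] <- P
  }
  list(positions = positions, flatten = P * spec$filters)
}

#' Build an untrained classifier
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases, unit
#' normalization gains) for the architecture in `spec` applied to encoded
#' inputs of shape `input_shape = c(positions, channels)`.
#'
#' @param spec A [cnn_spec()].
#' @param input_shape Integer vector `c(positions, channels)` of one encoded
#'   window, e.g. `scheme_shape("DNC")`.
#' @param seed Optional integer seed for the initialization; `NULL` uses the
#'   current RNG state.
#' @return An object of class `fourmc_cnn` (untrained: `$trained` is FALSE).
#' @export
build_cnn <- function(spec, input_shape, seed = NULL) {
  stopifnot(inherits(spec, "fourmc_cnn_spec"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2L || any(input_shape < 1L)) {
    abort("`input_shape` must be c(positions, channels), both positive")
  }
  if (!is.null(seed)) local_rng(seed)
  shapes <- chain_shapes(spec, input_shape)
  params <- list()
  c_in <- input_shape[2]
  k <- spec$kernel_size
  f <- spec$filters
  for (b in seq_len(spec$n_blocks)) {
    params[[paste0("conv", b)]] <- list(
      W = glorot_uniform(k * c_in, f, fan_in = k * c_in, fan_out = k * f),
      b = numeric(f)
    )
    params[[paste0("gn", b)]] <- list(gamma = rep(1, f), beta = numeric(f))
    c_in <- f
  }
  params$dense <- list(
    W = glorot_uniform(shapes$flatten, spec$dense_units,
                       fan_in = shapes$flatten, fan_out = spec$dense_units),
    b = numeric(spec$dense_units)
  )
  params$out <- list(
    W = glorot_uniform(spec$dense_units, 1L,
                       fan_in = spec$dense_units, fan_out = 1L),
    b = numeric(1)
  )
  structure(
    list(spec = spec, input_shape = input_shape, params = params,
         positions = shapes$positions, scheme = NULL, trained = FALSE,
         history = NULL),
    class = "fourmc_cnn"
  )
}

# Full forward pass. Returns per-sample logits/probabilities and the caches
# backward needs. train = TRUE enables dropout (drawing from the current RNG).
nn_forward <- function(net, X, train = FALSE) {
  spec <- net$spec
  caches <- list()
  H <- X
  for (b in seq_len(spec$n_blocks)) {
    cv <- conv_forward(H, net$params[[paste0("conv", b)]]$W,
                       net$params[[paste0("conv", b)]]$b, spec$kernel_size)
    A <- elu(cv$Y)
    gn <- gn_forward(A, net$params[[paste0("gn", b)]]$gamma,
                     net$params[[paste0("gn", b)]]$beta, spec$groups)
    pl <- pool_forward(gn$Y, spec$pool_size, spec$pool_stride)
    dr <- dropout_forward(pl$Y, spec$dropout, train)
    caches[[b]] <- list(X_in = H, conv = cv, preact = cv$Y, act = A,
                        gn = gn, pool = pl, drop = dr)
    H <- dr$Y
  }
  dH <- dim(H)
  flat <- H
  dim(flat) <- c(dH[1], dH[2] * dH[3])
  Z1 <- flat %*% net$params$dense$W + rep(net$params$dense$b, each = dH[1])
  A1 <- elu(Z1)
  logit <- drop(A1 %*% net$params$out$W) + net$params$out$b
  list(logit = logit, prob = sigmoid(logit),
       caches = caches, flat = flat, flat_dim = dH, Z1 = Z1, A1 = A1)
}

# Backward pass from d(loss)/d(logit). Returns parameter gradients (same
# structure as net$params) and the gradient with respect to the input batch.
nn_backward <- function(net, fw, dlogit) {
  spec <- net$spec
  n <- length(dlogit)
  grads <- list()
  dlog <- matrix(dlogit, n, 1)
  grads$out <- list(W = crossprod(fw$A1, dlog), b = sum(dlog))
  dA1 <- tcrossprod(dlog, net$params$out$W)
  dZ1 <- dA1 * elu_grad(fw$A1, fw$Z1)
  grads$dense <- list(W = crossprod(fw$flat, dZ1), b = colSums(dZ1))
  dflat <- tcrossprod(dZ1, net$params$dense$W)
  dH <- array(dflat, fw$flat_dim)
  for (b in rev(seq_len(spec$n_blocks))) {
    cache <- fw$caches[[b]]
    if (!is.null(cache$drop$mask)) dH <- dH * cache$drop$mask
    dP <- pool_backward(dH, cache$pool)
    gnb <- gn_backward(dP, cache$gn$xhat, cache$gn$inv,
                       net$params[[paste0("gn", b)]]$gamma, spec$groups)
    grads[[paste0("gn", b)]] <- list(gamma = gnb$dgamma, beta = gnb$dbeta)
    dA <- gnb$dX * elu_grad(cache$act, cache$preact)
    d_in <- dim(cache$X_in)
    cvb <- conv_backward(dA, cache$conv$M,
                         net$params[[paste0("conv", b)]]$W,
                         spec$kernel_size, d_in[1], d_in[2], d_in[3])
    grads[[paste0("conv", b)]] <- list(W = cvb$dW, b = cvb$db)
    dH <- cvb$dX
  }
  list(grads = grads, dX = dH)
}

# L2 penalty covers conv weights+biases and the first dense layer (not the
# normalization parameters, not the output layer).
l2_param_names <- function(spec) {
  c(paste0("conv", seq_len(spec$n_blocks)), "dense")
}

nn_loss <- function(net, X, y, train = FALSE) {
  fw <- nn_forward(net, X, train = train)
  n <- length(y)
  data_loss <- mean(softplus(fw$logit) - y * fw$logit)
  reg <- 0
  for (nm in l2_param_names(net$spec)) {
    reg <- reg + net$spec$l2_weight *
      (sum(net$params[[nm]]$W^2) + sum(net$params[[nm]]$b^2))
  }
  list(loss = data_loss + reg, data_loss = data_loss, fw = fw)
}

nn_loss_grads <- function(net, X, y, train = TRUE) {
  ls <- nn_loss(net, X, y, train = train)
  n <- length(y)
  dlogit <- (ls$fw$prob - y) / n
  bk <- nn_backward(net, ls$fw, dlogit)
  for (nm in l2_param_names(net$spec)) {
    bk$grads[[nm]]$W <- bk$grads[[nm]]$W + 2 * net$spec$l2_weight * net$params[[nm]]$W
    bk$grads[[nm]]$b <- bk$grads[[nm]]$b + 2 * net$spec$l2_weight * net$params[[nm]]$b
  }
  list(loss = ls$loss, prob = ls$fw$prob, grads = bk$grads, dX = bk$dX)
}

as_input_array <- function(net, newdata) {
  if (inherits(newdata, "fourmc_tensor")) {
    x <- newdata$x
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    x <- newdata
  } else if (is.data.frame(newdata)) {
    if (is.null(net$scheme)) {
      abort("model carries no encoding scheme; pass an encoded array instead")
    }
    x <- encode_dataset(newdata, net$scheme)$x
  } else {
    abort("`newdata` must be a fourmc_tensor, a 3-d array, or a data frame")
  }
  if (!identical(as.integer(dim(x)[2:3]), net$input_shape)) {
    abort(paste0(
      "input shape (", dim(x)[2], ", ", dim(x)[3],
      ") does not match the model's expected (",
      net$input_shape[1], ", ", net$input_shape[2], ")"
    ))
  }
  x
}

#' Train the classifier
#'
#' Minibatch SGD with momentum on binary cross-entropy, with per-epoch
#' validation, early stopping (patience epochs without validation-loss
#' improvement) and best-epoch checkpointing. Without a validation set the
#' training loss is monitored instead. Deterministic for a fixed
#' `config$seed` (weight initialization, shuffling and dropout all draw from
#' it); the caller's RNG state is left untouched.
#'
#' @param x Training inputs: a `fourmc_tensor` or `n x positions x channels`
#'   array.
#' @param y Binary labels aligned with `x` (taken from the tensor if `NULL`).
#' @param x_val,y_val Optional validation set, same conventions.
#' @param spec A [cnn_spec()].
#' @param config A [train_config()].
#' @param scheme Encoding scheme name to stamp on the model (taken from a
#'   `fourmc_tensor` automatically); needed later to re-encode raw sequences
#'   in [predict()][predict.fourmc_cnn] and the interpretation maps.
#' @return A trained `fourmc_cnn` with a `$history` tibble (epoch, loss,
#'   val_loss, acc, val_acc) and `$best_epoch`.
#' @export
train_cnn <- function(x, y = NULL, x_val = NULL, y_val = NULL,
                      spec = cnn_spec(), config = train_config(),
                      scheme = NULL) {
  if (inherits(x, "fourmc_tensor")) {
    if (is.null(y)) y <- x$y
    if (is.null(scheme)) scheme <- x$scheme
    x <- x$x
  }
  if (inherits(x_val, "fourmc_tensor")) {
    if (is.null(y_val)) y_val <- x_val$y
    x_val <- x_val$x
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  y <- as.numeric(y)
  if (length(y) != dim(x)[1]) abort("`x` and `y` lengths differ")
  if (!all(y %in% c(0, 1))) abort("labels must be binary")
  has_val <- !is.null(x_val)

  local_rng(config$seed)
  net <- build_cnn(spec, dim(x)[2:3])
  net$scheme <- scheme
  velocity <- rapply(net$params, function(p) p * 0, how = "replace")

  n <- dim(x)[1]
  best_loss <- Inf
  best_params <- net$params
  best_epoch <- 0L
  wait <- 0L
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    epoch_correct <- 0
    for (s in starts) {
      b_idx <- idx[s:min(s + config$batch_size - 1L, n)]
      res <- nn_loss_grads(net, x[b_idx, , , drop = FALSE], y[b_idx],
                           train = TRUE)
      epoch_loss <- epoch_loss + res$loss * length(b_idx)
      epoch_correct <- epoch_correct +
        sum((res$prob >= 0.5) == (y[b_idx] == 1))
      if (!is.finite(res$loss)) {
        abort(paste0(
          "training diverged: non-finite loss at epoch ", epoch,
          " (learning rate ", config$learning_rate, "); ",
          "lower the learning rate or check the encoded inputs"
        ))
      }
      for (nm in names(net$params)) {
        for (pn in names(net$params[[nm]])) {
          velocity[[nm]][[pn]] <- config$momentum * velocity[[nm]][[pn]] -
            config$learning_rate * res$grads[[nm]][[pn]]
          net$params[[nm]][[pn]] <- net$params[[nm]][[pn]] + velocity[[nm]][[pn]]
        }
      }
    }
    # epoch loss/accuracy are the sample-weighted means over the minibatch
    # passes (dropout active), the running-metric convention of the usual
    # training frameworks; validation metrics use a clean forward pass
    loss <- epoch_loss / n
    acc <- epoch_correct / n
    if (has_val) {
      vl <- nn_loss(net, x_val, y_val, train = FALSE)
      val_loss <- vl$loss
      val_acc <- mean((vl$fw$prob >= 0.5) == (y_val == 1))
    } else {
      val_loss <- NA_real_
      val_acc <- NA_real_
    }
    hist[[epoch]] <- tibble(epoch = epoch, loss = loss,
                            val_loss = val_loss, acc = acc, val_acc = val_acc)
    monitored <- if (has_val) val_loss else loss
    if (monitored < best_loss) {
      best_loss <- monitored
      best_params <- net$params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  if (config$checkpoint_best) net$params <- best_params
  net$trained <- TRUE
  net$history <- dplyr::bind_rows(hist)
  net$best_epoch <- best_epoch
  net$config <- config
  net
}

#' Train on a labelled window dataset
#'
#' Convenience wrapper: encodes `data` with `scheme`, optionally carves off a
#' stratified validation fraction, and calls [train_cnn()].
#'
#' @param data A data frame with columns `id`, `seq`, `label`.
#' @param scheme Encoding scheme name.
#' @param spec,config See [train_cnn()].
#' @param val_fraction Fraction held out (stratified) for validation-based
#'   early stopping; 0 disables validation.
#' @return A trained `fourmc_cnn`.
#' @export
train_on_windows <- function(data, scheme, spec = cnn_spec(),
                             config = train_config(), val_fraction = 0.1) {
  if (val_fraction > 0) {
    parts <- split_dataset(data, train_fraction = 1 - val_fraction,
                           seed = config$seed)
    # split_dataset()'s "train" fraction is the larger share; validation is
    # the complement here
    tr <- encode_dataset(parts$train, scheme)
    va <- encode_dataset(parts$test, scheme)
    train_cnn(tr, x_val = va, spec = spec, config = config)
  } else {
    train_cnn(encode_dataset(data, scheme), spec = spec, config = config)
  }
}

#' Predict 4mC probabilities
#'
#' @param object A trained `fourmc_cnn`.
#' @param newdata A `fourmc_tensor`, a 3-d array, or a data frame of raw
#'   windows (re-encoded with the model's stored scheme).
#' @param ... Unused.
#' @return A numeric vector of probabilities in \[0, 1\].
#' @export
predict.fourmc_cnn <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) {
    abort("model is untrained; call train_cnn() first")
  }
  x <- as_input_array(object, newdata)
  nn_forward(object, x, train = FALSE)$prob
}

#' Gradient of the pre-sigmoid logit with respect to the encoded input
#'
#' The raw ingredient of gradient-times-input saliency. Differentiates the
#' logit (not the probability) to avoid vanishing gradients at saturated
#' outputs.
#'
#' @param net A trained `fourmc_cnn`.
#' @param x A 3-d input array or `fourmc_tensor`.
#' @return An array of the same shape as the input batch.
#' @export
input_gradient <- function(net, x) {
  x <- as_input_array(net, x)
  fw <- nn_forward(net, x, train = FALSE)
  nn_backward(net, fw, rep(1, dim(x)[1]))$dX
}

#' Number of learnable parameters
#'
#' @param net A `fourmc_cnn`.
#' @return Integer parameter count (a pure function of the architecture and
#'   input shape).
#' @export
n_params <- function(net) {
  sum(rapply(net$params, length, how = "unlist"))
}

#' @export
print.fourmc_cnn <- function(x, ...) {
  cat("<fourmc_cnn> ", x$spec$n_blocks, " block(s), ", x$spec$filters,
      " filters, kernel ", x$spec$kernel_size, "; input (",
      x$input_shape[1], ", ", x$input_shape[2], "); ",
      format(n_params(x), big.mark = ","), " parameters; ",
      if (isTRUE(x$trained)) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Save / load a trained model as a JSON archive
#'
#' The archive holds the architecture, input shape, scheme and all parameter
#' arrays as full-precision text; [load_cnn()] restores an identical
#' predictor.
#'
#' @param net A `fourmc_cnn`.
#' @param path Archive path.
#' @return `path` (save) or the restored `fourmc_cnn` (load).
#' @export
save_cnn <- function(net, path) {
  flat <- rapply(net$params, function(p) list(dim = dim(p), v = as.numeric(p)),
                 how = "list")
  obj <- list(
    spec = unclass(net$spec), input_shape = net$input_shape,
    scheme = net$scheme, trained = net$trained, params = flat
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(cnn_spec, obj$spec)
  net <- build_cnn(spec, obj$input_shape, seed = 0L)
  for (nm in names(net$params)) {
    for (pn in names(net$params[[nm]])) {
      st <- obj$params[[nm]][[pn]]
      v <- as.numeric(st$v)
      if (!is.null(st$dim) && length(st$dim) > 0) dim(v) <- unlist(st$dim)
      net$params[[nm]][[pn]] <- v
    }
  }
  net$scheme <- obj$scheme
  net$trained <- isTRUE(obj$trained)
  net
}
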