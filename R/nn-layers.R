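## Internal layer primitives for the 1-D convolutional classifier.
##
## Batches are 3-d arrays (n, positions, channels), column-major with the
## sample index fastest. Every flattening below relies on that layout:
## dim(a) <- c(n * P, C) maps element (i, p, c) to row i + (p-1)*n, column c.
## All forward functions return the caches their backward partner needs;
## backward functions return parameter gradients plus the gradient with
## respect to their input, so the chain also yields d(logit)/d(input) for
## saliency maps.

elu <- function(x) {
  y <- x
  neg <- x <= 0
  y[neg] <- exp(x[neg]) - 1
  y
}

elu_grad <- function(y, x) {
  # derivative expressed via the activation value: 1 for x > 0, y + 1 below
  g <- array(1, dim(x))
  neg <- x <= 0
  g[neg] <- y[neg] + 1
  g
}

glorot_uniform <- function(n_row, n_col, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(n_row * n_col, -limit, limit), n_row, n_col)
}

## ---- 1-D convolution, stride 1, "same" padding -------------------------

conv_forward <- function(X, W, b, k) {
  d <- dim(X); n <- d[1]; P <- d[2]; C <- d[3]
  f <- ncol(W)
  pl <- (k - 1L) %/% 2L
  Xp <- array(0, c(n, P + k - 1L, C))
  Xp[, pl + seq_len(P), ] <- X
  M <- matrix(0, n * P, k * C)
  for (j in seq_len(k)) {
    sl <- Xp[, seq_len(P) + j - 1L, , drop = FALSE]
    dim(sl) <- c(n * P, C)
    M[, ((j - 1L) * C + 1L):(j * C)] <- sl
  }
  Ym <- M %*% W + rep(b, each = n * P)
  list(Y = array(Ym, c(n, P, f)), M = M)
}

conv_backward <- function(dY, M, W, k, n, P, C) {
  f <- ncol(W)
  dYm <- matrix(dY, n * P, f)
  dW <- crossprod(M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)
  pl <- (k - 1L) %/% 2L
  dXp <- array(0, c(n, P + k - 1L, C))
  for (j in seq_len(k)) {
    sl <- dM[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    dim(sl) <- c(n, P, C)
    idx <- seq_len(P) + j - 1L
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + sl
  }
  list(dW = dW, db = db, dX = dXp[, pl + seq_len(P), , drop = FALSE])
}

## ---- group normalization ----------------------------------------------
## Normalizes each sample over (positions x channels-in-group); gamma/beta
## are per-channel. Population variance, epsilon 1e-5.

gn_forward <- function(X, gamma, beta, groups, eps = 1e-5) {
  d <- dim(X); n <- d[1]; P <- d[2]; C <- d[3]
  cg <- C %/% groups
  Y <- array(0, d)
  xhat_all <- array(0, d)
  inv_all <- matrix(0, n, groups)
  for (gi in seq_len(groups)) {
    ch <- ((gi - 1L) * cg + 1L):(gi * cg)
    sub <- X[, , ch, drop = FALSE]
    dim(sub) <- c(n, P * cg)
    mu <- rowMeans(sub)
    v <- rowMeans(sub * sub) - mu * mu
    inv <- 1 / sqrt(v + eps)
    xhat <- (sub - mu) * inv
    xa <- array(xhat, c(n, P, cg))
    Y[, , ch] <- sweep(sweep(xa, 3, gamma[ch], "*"), 3, beta[ch], "+")
    xhat_all[, , ch] <- xa
    inv_all[, gi] <- inv
  }
  list(Y = Y, xhat = xhat_all, inv = inv_all)
}

gn_backward <- function(dY, xhat, inv, gamma, groups) {
  d <- dim(dY); n <- d[1]; P <- d[2]; C <- d[3]
  cg <- C %/% groups
  m <- P * cg
  dX <- array(0, d)
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  for (gi in seq_len(groups)) {
    ch <- ((gi - 1L) * cg + 1L):(gi * cg)
    dy <- dY[, , ch, drop = FALSE];  dim(dy) <- c(n, m)
    xh <- xhat[, , ch, drop = FALSE]; dim(xh) <- c(n, m)
    e <- dy * xh
    dim(e) <- c(n * P, cg); dgamma[ch] <- colSums(e)
    db <- dy; dim(db) <- c(n * P, cg); dbeta[ch] <- colSums(db)
    # dxhat = dy * gamma (per channel; columns are position-fastest blocks)
    gcol <- rep(gamma[ch], each = P)
    dxh <- dy * rep(gcol, each = n)
    s1 <- rowSums(dxh)
    s2 <- rowSums(dxh * xh)
    dx <- inv[, gi] * (dxh - (s1 + xh * s2) / m)
    dX[, , ch] <- array(dx, c(n, P, cg))
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- max pooling, "same" padding (TF-style: extra pad on the right) ----

pool_out_len <- function(P, stride) as.integer(ceiling(P / stride))

pool_forward <- function(X, l, r) {
  d <- dim(X); n <- d[1]; P <- d[2]; C <- d[3]
  P1 <- pool_out_len(P, r)
  pad <- max((P1 - 1L) * r + l - P, 0L)
  pl <- pad %/% 2L
  Pp <- P + pad
  Xp <- array(-Inf, c(n, Pp, C))
  Xp[, pl + seq_len(P), ] <- X
  starts <- (seq_len(P1) - 1L) * r + 1L
  best <- array(-Inf, c(n, P1, C))
  arg <- array(1L, c(n, P1, C))
  for (j in seq_len(l)) {
    cand <- Xp[, starts + j - 1L, , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(Y = best, arg = arg, pl = pl, Pp = Pp, P = P, r = r, l = l)
}

pool_backward <- function(dY, cache) {
  d <- dim(dY); n <- d[1]; P1 <- d[2]; C <- d[3]
  dXp <- array(0, c(n, cache$Pp, C))
  starts <- (seq_len(P1) - 1L) * cache$r + 1L
  for (j in seq_len(cache$l)) {
    idx <- starts + j - 1L
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dY * (cache$arg == j)
  }
  dXp[, cache$pl + seq_len(cache$P), , drop = FALSE]
}

## ---- dropout (inverted scaling at train time) --------------------------

dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) {
    return(list(Y = X, mask = NULL))
  }
  keep <- 1 - rate
  mask <- array((runif(length(X)) < keep) / keep, dim(X))
  list(Y = X * mask, mask = mask)
}

softplus <- function(z) log1p(exp(-abs(z))) + pmax(z, 0)

sigmoid <- function(z) 1 / (1 + exp(-z))
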