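# Neural-network primitives on base matrix algebra.
#
# Data layout: activations are 3-D arrays [channels, time, batch]. All
# convolutions run as im2col + one GEMM per batch; gradients are derived by
# hand and checked against finite differences in the test suite. No deep
# learning framework is used, which keeps runs bit-deterministic given the
# seed.

# ---- parameter initialization -------------------------------------------

# Standard fan-in-scaled uniform initialization, U(-1/sqrt(fan_in), +).
init_uniform <- function(nrow, ncol, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

# Weight-normalized causal conv layer: V is the direction tensor stored flat
# as [c_out, c_in * k] (tap-major columns), g the per-output-row gain, b the
# bias. The effective weight is W = diag(g / ||V_row||) V.
init_wn_conv <- function(c_in, c_out, k) {
  fan_in <- c_in * k
  V <- init_uniform(c_out, fan_in, fan_in)
  structure(list(V = V, g = sqrt(rowSums(V^2)),
                 b = stats::runif(c_out, -1 / sqrt(fan_in), 1 / sqrt(fan_in)),
                 k = as.integer(k), c_in = as.integer(c_in)),
            class = "wn_conv")
}

init_dense <- function(n_in, n_out) {
  structure(list(W = init_uniform(n_out, n_in, n_in),
                 b = stats::runif(n_out, -1 / sqrt(n_in), 1 / sqrt(n_in))),
            class = "dense")
}

# Plain (non-normalized) conv layer, used by the CNN baseline and shortcuts.
init_conv <- function(c_in, c_out, k) {
  fan_in <- c_in * k
  structure(list(W = init_uniform(c_out, fan_in, fan_in),
                 b = stats::runif(c_out, -1 / sqrt(fan_in), 1 / sqrt(fan_in)),
                 k = as.integer(k), c_in = as.integer(c_in)),
            class = "conv")
}

# Effective weight of a conv layer, whether weight-normalized (V, g) or
# plain (W).
layer_weight <- function(layer) {
  if (!is.null(layer$V)) wn_weight(layer) else layer$W
}

wn_weight <- function(layer) {
  nrm <- sqrt(rowSums(layer$V^2))
  layer$V * (layer$g / pmax(nrm, 1e-12))
}

# Backprop through the weight-norm reparameterization: given dW, return
# gradients for V and g.
wn_backward <- function(layer, dW) {
  nrm <- pmax(sqrt(rowSums(layer$V^2)), 1e-12)
  s <- rowSums(dW * layer$V)
  list(V = dW * (layer$g / nrm) - layer$V * (layer$g * s / nrm^3),
       g = s / nrm)
}

# ---- 1-D convolution (im2col) -------------------------------------------

# Pad a [C, T, B] array with zeros on the time axis.
pad_time <- function(X, left, right) {
  d <- dim(X)
  if (left == 0L && right == 0L) return(X)
  Xp <- array(0, dim = c(d[1L], d[2L] + left + right, d[3L]))
  Xp[, left + seq_len(d[2L]), ] <- X
  Xp
}

# im2col for dilated conv: rows are (tap 1 channels, tap 2 channels, ...),
# columns are (time within sample) x (sample within batch).
im2col <- function(Xp, Tout, k, d) {
  dm <- dim(Xp)
  C <- dm[1L]; B <- dm[3L]
  M <- matrix(0, nrow = C * k, ncol = Tout * B)
  for (j in seq_len(k)) {
    sl <- Xp[, (j - 1L) * d + seq_len(Tout), , drop = FALSE]
    dim(sl) <- c(C, Tout * B)
    M[(j - 1L) * C + seq_len(C), ] <- sl
  }
  M
}

col2im <- function(dM, dims_pad, Tout, k, d) {
  C <- dims_pad[1L]; B <- dims_pad[3L]
  dXp <- array(0, dim = dims_pad)
  for (j in seq_len(k)) {
    blk <- dM[(j - 1L) * C + seq_len(C), , drop = FALSE]
    dim(blk) <- c(C, Tout, B)
    idx <- (j - 1L) * d + seq_len(Tout)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + blk
  }
  dXp
}

# Forward conv with an explicit flat weight [c_out, c_in * k]. `pad_left`
# = d * (k - 1) gives a causal layer (output t sees inputs <= t only);
# symmetric padding gives the ordinary "same" conv of the CNN baseline.
conv1d_forward <- function(X, W, b, k, d, pad_left, pad_right = 0L) {
  dm <- dim(X)
  Tt <- dm[2L]; B <- dm[3L]
  Tout <- Tt + pad_left + pad_right - d * (k - 1L)
  Xp <- pad_time(X, pad_left, pad_right)
  M <- im2col(Xp, Tout, k, d)
  Y <- W %*% M + b
  dim(Y) <- c(nrow(W), Tout, B)
  list(Y = Y, M = M, dims_pad = dim(Xp), Tout = Tout)
}

conv1d_backward <- function(dY, W, cache, k, d, pad_left, Tin) {
  dm <- dim(dY)
  dY2 <- dY; dim(dY2) <- c(dm[1L], dm[2L] * dm[3L])
  dW <- dY2 %*% t(cache$M)
  db <- rowSums(dY2)
  dM <- crossprod(W, dY2)
  dXp <- col2im(dM, cache$dims_pad, cache$Tout, k, d)
  dX <- dXp[, pad_left + seq_len(Tin), , drop = FALSE]
  list(dW = dW, db = db, dX = dX)
}

# ---- elementwise pieces --------------------------------------------------

relu_fwd <- function(X) { X[X < 0] <- 0; X }
relu_bwd <- function(dY, Y) { dY[Y <= 0] <- 0; dY }

apply_activation <- function(X, activation) {
  switch(activation,
         relu = relu_fwd(X),
         sigmoid = 1 / (1 + exp(-X)),
         tanh = tanh(X),
         stopf("unknown activation '%s'", activation))
}

activation_bwd <- function(dY, Y, activation) {
  switch(activation,
         relu = relu_bwd(dY, Y),
         sigmoid = dY * Y * (1 - Y),
         tanh = dY * (1 - Y^2),
         stopf("unknown activation '%s'", activation))
}

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- array(stats::rbinom(length(X), 1L, 1 - p) / (1 - p), dim = dim(X))
  list(Y = X * mask, mask = mask)
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

col_softmax <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

# ---- residual TCN block --------------------------------------------------

block_forward <- function(params, X, d, activation, dropout, training) {
  Tt <- dim(X)[2L]
  k <- params$conv1$k
  pad <- d * (k - 1L)

  c1 <- conv1d_forward(X, layer_weight(params$conv1), params$conv1$b, k, d, pad)
  a1 <- apply_activation(c1$Y, activation)
  d1 <- dropout_fwd(a1, dropout, training)

  c2 <- conv1d_forward(d1$Y, layer_weight(params$conv2), params$conv2$b, k, d, pad)
  a2 <- apply_activation(c2$Y, activation)
  d2 <- dropout_fwd(a2, dropout, training)

  if (!is.null(params$shortcut)) {
    sc <- conv1d_forward(X, params$shortcut$W, params$shortcut$b, 1L, 1L, 0L)
    res <- sc$Y
  } else {
    sc <- NULL
    res <- X
  }
  O <- apply_activation(res + d2$Y, activation)
  list(Y = O,
       cache = list(X = X, c1 = c1, a1 = a1, d1 = d1, c2 = c2, a2 = a2,
                    d2 = d2, sc = sc, O = O, d = d, k = k, pad = pad, T = Tt))
}

block_backward <- function(params, cache, dO, activation, training) {
  dsum <- activation_bwd(dO, cache$O, activation)
  grads <- list()

  # main branch
  conv_grads <- function(layer, dW, db) {
    if (!is.null(layer$V)) {
      gw <- wn_backward(layer, dW)
      list(V = gw$V, g = gw$g, b = db)
    } else {
      list(W = dW, b = db)
    }
  }

  dd2 <- if (!is.null(cache$d2$mask)) dsum * cache$d2$mask else dsum
  da2 <- activation_bwd(dd2, cache$a2, activation)
  b2 <- conv1d_backward(da2, layer_weight(params$conv2), cache$c2,
                        cache$k, cache$d, cache$pad, cache$T)
  grads$conv2 <- conv_grads(params$conv2, b2$dW, b2$db)

  dd1 <- if (!is.null(cache$d1$mask)) b2$dX * cache$d1$mask else b2$dX
  da1 <- activation_bwd(dd1, cache$a1, activation)
  b1 <- conv1d_backward(da1, layer_weight(params$conv1), cache$c1,
                        cache$k, cache$d, cache$pad, cache$T)
  grads$conv1 <- conv_grads(params$conv1, b1$dW, b1$db)

  dX <- b1$dX
  if (!is.null(params$shortcut)) {
    bs <- conv1d_backward(dsum, params$shortcut$W, cache$sc, 1L, 1L, 0L, cache$T)
    grads$shortcut <- list(W = bs$dW, b = bs$db)
    dX <- dX + bs$dX
  } else {
    dX <- dX + dsum
  }
  list(grads = grads, dX = dX)
}

# ---- scaled dot-product self-attention ----------------------------------

# Forward over a batch: learned Q/K/V projections of the feature sequence
# (time-major within each sample), softmax(Q K^T / sqrt(d_m)) V, and a
# residual addition of the input sequence.
attention_forward <- function(params, X) {
  dm_ <- dim(X)
  C <- dm_[1L]; Tt <- dm_[2L]; B <- dm_[3L]
  d_m <- ncol(params$Wq)
  Y <- array(0, dim = c(C, Tt, B))
  caches <- vector("list", B)
  s <- sqrt(d_m)
  for (bb in seq_len(B)) {
    H <- t(X[, , bb])                                   # [T, C]
    Q <- H %*% params$Wq + rep(params$bq, each = Tt)
    K <- H %*% params$Wk + rep(params$bk, each = Tt)
    V <- H %*% params$Wv + rep(params$bv, each = Tt)
    A <- row_softmax(Q %*% t(K) / s)
    O <- A %*% V
    Y[, , bb] <- t(H + O)
    caches[[bb]] <- list(H = H, Q = Q, K = K, V = V, A = A)
  }
  list(Y = Y, caches = caches)
}

attention_backward <- function(params, caches, dY) {
  d_m <- ncol(params$Wq)
  s <- sqrt(d_m)
  B <- dim(dY)[3L]
  z <- function(m) array(0, dim = dim(m))
  g <- list(Wq = z(params$Wq), bq = numeric(length(params$bq)),
            Wk = z(params$Wk), bk = numeric(length(params$bk)),
            Wv = z(params$Wv), bv = numeric(length(params$bv)))
  dX <- array(0, dim = dim(dY))
  for (bb in seq_len(B)) {
    ca <- caches[[bb]]
    dOut <- t(dY[, , bb])                               # [T, C]
    dH <- dOut
    dA <- dOut %*% t(ca$V)
    dV <- crossprod(ca$A, dOut)
    dZ <- ca$A * (dA - rowSums(dA * ca$A))
    dQ <- dZ %*% ca$K / s
    dK <- crossprod(dZ, ca$Q) / s
    g$Wq <- g$Wq + crossprod(ca$H, dQ); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(ca$H, dK); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(ca$H, dV); g$bv <- g$bv + colSums(dV)
    dH <- dH + tcrossprod(dQ, params$Wq) + tcrossprod(dK, params$Wk) +
      tcrossprod(dV, params$Wv)
    dX[, , bb] <- t(dH)
  }
  list(grads = g, dX = dX)
}

# ---- pooling and head ----------------------------------------------------

gap_forward <- function(X) {
  Y <- apply(X, 3L, rowMeans)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  Y                                                    # [C, B]
}

gap_backward <- function(dY, dims) {
  Tt <- dims[2L]
  dX <- array(0, dim = dims)
  for (bb in seq_len(dims[3L])) dX[, , bb] <- matrix(dY[, bb], dims[1L], Tt) / Tt
  dX
}

avgpool2_forward <- function(X) {
  d <- dim(X)
  Tout <- d[2L] %/% 2L
  idx <- seq_len(Tout) * 2L
  Y <- (X[, idx - 1L, , drop = FALSE] + X[, idx, , drop = FALSE]) / 2
  Y
}

avgpool2_backward <- function(dY, dims) {
  dX <- array(0, dim = dims)
  Tout <- dim(dY)[2L]
  idx <- seq_len(Tout) * 2L
  dX[, idx - 1L, ] <- dY / 2
  dX[, idx, ] <- dY / 2
  dX
}
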