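#' Architecture configuration
#'
#' All hyper-parameters of the self-attentive TCN and its baselines. The
#' reference clinical configuration is the default: a 19 x 200 input, two
#' residual blocks of two weight-normalized causal dilated convolutions
#' (kernel 4, dilation 2^i at level i), hidden width 164, a single-head
#' scaled dot-product self-attention stage of the same width, global average
#' pooling and a 2-unit softmax head. With these defaults the network has
#' 420,662 trainable parameters (0.42 M).
#'
#' @param n_levels number of residual blocks (level i uses dilation
#'   `dilation_base^i`, i from 0).
#' @param kernel_size convolution kernel size k.
#' @param hidden_width channel width C of the residual blocks; also the
#'   attention dimension d_m.
#' @param dilation_base base of the per-level dilation growth.
#' @param dropout dropout probability inside residual blocks.
#' @param attention_dim attention width d_m; must equal `hidden_width`.
#' @param n_classes number of output classes (2: healthy vs EP).
#' @param in_channels input channels (19 clinical, 1 single-channel).
#' @param in_length input segment length in samples (200 or 100).
#' @param activation activation inside blocks: "relu", "sigmoid" or "tanh".
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_levels = 2, kernel_size = 4, hidden_width = 164,
                         dilation_base = 2, dropout = 0.1,
                         attention_dim = hidden_width, n_classes = 2,
                         in_channels = 19, in_length = 200,
                         activation = c("relu", "sigmoid", "tanh")) {
  activation <- match.arg(activation)
  for (nm in c("n_levels", "kernel_size", "hidden_width", "dilation_base",
               "attention_dim", "n_classes", "in_channels", "in_length")) {
    v <- get(nm)
    if (!is_count(v)) stopf("`%s` must be a positive integer", nm)
  }
  if (!is_scalar_num(dropout) || dropout < 0 || dropout >= 1)
    stopf("`dropout` must be in [0, 1)")
  if (attention_dim != hidden_width)
    stopf("`attention_dim` must equal `hidden_width` (d_m = C)")
  if (n_classes != 2) stopf("only binary classification is supported")
  structure(list(n_levels = as.integer(n_levels),
                 kernel_size = as.integer(kernel_size),
                 hidden_width = as.integer(hidden_width),
                 dilation_base = as.integer(dilation_base),
                 dropout = as.double(dropout),
                 attention_dim = as.integer(attention_dim),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 in_length = as.integer(in_length),
                 activation = activation),
            class = "model_config")
}

#' Historical span added by one causal dilated convolution layer
#'
#' A causal convolution with dilation `d` and kernel size `k` lets the output
#' at time t reach back `d * (k - 1)` samples.
#'
#' @param d dilation factor (>= 1).
#' @param k kernel size (>= 1).
#' @return `d * (k - 1)`, in samples.
#' @export
receptive_span <- function(d, k) {
  if (!is_count(d) || !is_count(k)) stopf("`d` and `k` must be positive integers")
  d * (k - 1)
}

#' Total receptive field of the stacked residual blocks
#'
#' One sample plus the span contributed by every causal dilated layer: each
#' of the `n_levels` blocks holds two layers at dilation `dilation_base^i`.
#'
#' @param config a [model_config()].
#' @return Receptive field in samples.
#' @export
receptive_field <- function(config) {
  spans <- vapply(seq_len(config$n_levels) - 1L, function(i)
    2L * receptive_span(config$dilation_base^i, config$kernel_size), numeric(1))
  1 + sum(spans)
}

# Flatten a [c_out, c_in, k] kernel to the tap-major [c_out, c_in * k]
# layout used by the im2col convolution.
flatten_kernel <- function(Wk) {
  d <- dim(Wk)
  W <- matrix(0, d[1L], d[2L] * d[3L])
  for (j in seq_len(d[3L]))
    W[, (j - 1L) * d[2L] + seq_len(d[2L])] <- Wk[, , j]
  W
}

#' Causal dilated convolution of a sequence
#'
#' Left-zero-padded convolution: the output has the input's length and the
#' value at time t depends only on inputs at times <= t, reaching back
#' `dilation * (k - 1)` samples. The last kernel tap multiplies the current
#' sample.
#'
#' @param x numeric vector (one channel) or matrix channels x time.
#' @param weights numeric vector of length k (single in/out channel) or a
#'   3-D array `[c_out, c_in, k]`.
#' @param bias optional per-output-channel bias (default zero).
#' @param dilation positive integer dilation factor.
#' @return A vector (vector input, one output channel) or a
#'   `[c_out, time]` matrix.
#' @export
causal_dilated_conv <- function(x, weights, bias = NULL, dilation = 1) {
  if (!is_count(dilation)) stopf("`dilation` must be a positive integer")
  was_vec <- is.null(dim(x))
  if (was_vec) x <- matrix(x, nrow = 1L)
  if (is.null(dim(weights))) {
    if (nrow(x) != 1L)
      stopf("vector weights imply one input channel; x has %d", nrow(x))
    weights <- array(weights, dim = c(1L, 1L, length(weights)))
  }
  dw <- dim(weights)
  if (length(dw) != 3L) stopf("`weights` must be a vector or [c_out, c_in, k] array")
  if (dw[2L] != nrow(x))
    stopf("kernel expects %d input channels, x has %d", dw[2L], nrow(x))
  k <- dw[3L]
  if (is.null(bias)) bias <- numeric(dw[1L])
  X <- array(x, dim = c(nrow(x), ncol(x), 1L))
  out <- conv1d_forward(X, flatten_kernel(weights), bias, k, dilation,
                        pad_left = dilation * (k - 1L))
  Y <- out$Y[, , 1L, drop = FALSE]
  dim(Y) <- dim(Y)[1:2]
  if (was_vec && dw[1L] == 1L) as.vector(Y) else Y
}

# Coerce a user-supplied conv description (list(W = [c_out, c_in, k] array,
# b = bias) or an internal wn_conv) into an internal layer.
as_conv_layer <- function(spec) {
  if (inherits(spec, "wn_conv") || !is.null(spec$V)) return(spec)
  Wk <- spec$W
  if (length(dim(Wk)) != 3L) stopf("conv weights must be a [c_out, c_in, k] array")
  d <- dim(Wk)
  list(W = flatten_kernel(Wk), b = spec$b %||% numeric(d[1L]),
       k = as.integer(d[3L]), c_in = as.integer(d[2L]))
}

#' Residual TCN block
#'
#' `o = activation(x + F(x))` where F is two causal dilated convolution
#' layers (each followed by the activation and, in training, dropout). When
#' the input and hidden widths differ a 1x1 convolution matches the shortcut
#' to the branch width. Input and output lengths are identical.
#'
#' @param x numeric matrix channels x time (vector = one channel).
#' @param params list with elements `conv1`, `conv2` (each `list(W, b)` with
#'   `W` a `[c_out, c_in, k]` array) and optional `shortcut`
#'   (`list(W, b)` with a `[c_out, c_in, 1]` array).
#' @param dilation dilation factor of both layers.
#' @param activation activation name.
#' @return Matrix channels x time.
#' @export
residual_block <- function(x, params, dilation = 1, activation = "relu") {
  if (!is_count(dilation)) stopf("`dilation` must be a positive integer")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  layers <- list(conv1 = as_conv_layer(params$conv1),
                 conv2 = as_conv_layer(params$conv2),
                 shortcut = if (!is.null(params$shortcut)) {
                   sc <- as_conv_layer(params$shortcut)
                   list(W = sc$W, b = sc$b)
                 })
  X <- array(x, dim = c(nrow(x), ncol(x), 1L))
  out <- block_forward(layers, X, dilation, activation, dropout = 0,
                       training = FALSE)
  Y <- out$Y[, , 1L, drop = FALSE]
  dim(Y) <- dim(Y)[1:2]
  Y
}

#' Scaled dot-product self-attention
#'
#' `attention(Q, M, V) = softmax(Q M^T / sqrt(d_m)) V`, applied row-wise:
#' every output row is a convex combination of the value rows, weighted by
#' the normalized similarity of the corresponding query to all keys.
#'
#' @param Q,M,V query, key and value matrices, each sequence x d_m.
#' @return List with `output` (sequence x d_m matrix) and `weights` (the
#'   attention matrix; every row sums to 1).
#' @export
self_attention <- function(Q, M, V) {
  Q <- as.matrix(Q); M <- as.matrix(M); V <- as.matrix(V)
  d_m <- ncol(M)
  if (d_m < 1L) stopf("attention dimension d_m must be positive")
  if (ncol(Q) != d_m || ncol(V) != d_m ||
      nrow(Q) != nrow(M) || nrow(M) != nrow(V))
    stopf("Q, M, V must share sequence length and width d_m")
  A <- row_softmax(Q %*% t(M) / sqrt(d_m))
  list(output = A %*% V, weights = A)
}

# ---- model construction --------------------------------------------------

init_blocks <- function(cfg) {
  blocks <- vector("list", cfg$n_levels)
  c_in <- cfg$in_channels
  for (i in seq_len(cfg$n_levels)) {
    blk <- list(conv1 = init_wn_conv(c_in, cfg$hidden_width, cfg$kernel_size),
                conv2 = init_wn_conv(cfg$hidden_width, cfg$hidden_width,
                                     cfg$kernel_size),
                shortcut = if (c_in != cfg$hidden_width)
                  init_conv(c_in, cfg$hidden_width, 1L))
    blocks[[i]] <- blk
    c_in <- cfg$hidden_width
  }
  blocks
}

init_attention <- function(cfg) {
  C <- cfg$hidden_width
  list(Wq = init_uniform(C, C, C), bq = stats::runif(C, -1 / sqrt(C), 1 / sqrt(C)),
       Wk = init_uniform(C, C, C), bk = stats::runif(C, -1 / sqrt(C), 1 / sqrt(C)),
       Wv = init_uniform(C, C, C), bv = stats::runif(C, -1 / sqrt(C), 1 / sqrt(C)))
}

new_model <- function(kind, config, params) {
  structure(list(kind = kind, config = config, params = params),
            class = "eeg_model")
}

#' Build the self-attentive TCN classifier
#'
#' Pipeline: stacked residual blocks of causal dilated convolutions
#' (dilation `dilation_base^i` at level i) -> single-head self-attention over
#' the feature sequence with learned Q/K/V projections and a residual
#' addition -> global average pooling over time -> linear map to 2 units ->
#' softmax. Pooling keeps the parameter count independent of the input
#' length, so the same configuration serves 200- and 100-sample segments.
#'
#' @param config a [model_config()].
#' @param seed seed for the fan-in-scaled uniform weight initialization.
#' @return Object of class `eeg_model`.
#' @export
build_model <- function(config = model_config(), seed = 1) {
  if (!inherits(config, "model_config")) stopf("`config` must be a model_config")
  with_seed(seed, {
    params <- list(blocks = init_blocks(config),
                   attn = init_attention(config),
                   head = init_dense(config$hidden_width, config$n_classes))
    new_model("tcnsa", config, params)
  })
}

#' Build a comparison baseline
#'
#' Three reference architectures sharing the training loop and head of the
#' main model: `"tcn"` is the residual TCN without the attention stage;
#' `"sa"` is a per-timestep linear embedding followed by self-attention;
#' `"cnn"` is two ordinary (non-causal) convolution + average-pooling stages.
#' All end in global average pooling and a 2-unit softmax.
#'
#' @param kind `"tcn"`, `"sa"` or `"cnn"`.
#' @param config a [model_config()].
#' @param seed initialization seed.
#' @return Object of class `eeg_model`.
#' @export
build_baseline <- function(kind = c("tcn", "sa", "cnn"),
                           config = model_config(), seed = 1) {
  kind <- match.arg(kind)
  if (!inherits(config, "model_config")) stopf("`config` must be a model_config")
  C <- config$hidden_width
  with_seed(seed, {
    params <- switch(kind,
      tcn = list(blocks = init_blocks(config),
                 head = init_dense(C, config$n_classes)),
      sa = list(embed = init_conv(config$in_channels, C, 1L),
                attn = init_attention(config),
                head = init_dense(C, config$n_classes)),
      cnn = list(conv1 = init_conv(config$in_channels, C, config$kernel_size),
                 conv2 = init_conv(C, C, config$kernel_size),
                 head = init_dense(C, config$n_classes)))
    new_model(kind, config, params)
  })
}

#' @export
print.eeg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<eeg_model> kind=%s: input %d x %d, levels=%d, k=%d, width=%d\n",
              x$kind, cfg$in_channels, cfg$in_length, cfg$n_levels,
              cfg$kernel_size, cfg$hidden_width))
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums all trainable weight and bias scalars. A weight-normalized layer is
#' counted as its underlying weight tensor plus bias only (the scalar gains
#' of the reparameterization are not counted separately). The reference
#' clinical configuration counts 420,662 scalars, i.e. 0.42 M.
#'
#' @param model an `eeg_model`, or a bare parameter list (e.g.
#'   `list(W = ..., b = ...)` for a lone linear map).
#' @return Integer total.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "eeg_model")) model$params else model
  counted <- c("V", "W", "b", "Wq", "bq", "Wk", "bk", "Wv", "bv")
  count_tree <- function(x) {
    if (!is.list(x)) return(0)
    nms <- names(x) %||% rep("", length(x))
    tot <- 0
    for (i in seq_along(x)) {
      el <- x[[i]]
      if (is.list(el)) tot <- tot + count_tree(el)
      else if (is.numeric(el) && nms[i] %in% counted) tot <- tot + length(el)
    }
    tot
  }
  as.integer(count_tree(params))
}

# ---- forward / backward dispatch ----------------------------------------

model_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  act <- cfg$activation
  cache <- list()
  H <- X

  if (model$kind %in% c("tcnsa", "tcn")) {
    bl <- vector("list", length(p$blocks))
    for (i in seq_along(p$blocks)) {
      d <- cfg$dilation_base^(i - 1L)
      r <- block_forward(p$blocks[[i]], H, d, act, cfg$dropout, training)
      H <- r$Y
      bl[[i]] <- r$cache
    }
    cache$blocks <- bl
    if (model$kind == "tcnsa") {
      at <- attention_forward(p$attn, H)
      cache$attn <- at$caches
      cache$attn_dims <- dim(H)
      H <- at$Y
    }
  } else if (model$kind == "sa") {
    e <- conv1d_forward(H, p$embed$W, p$embed$b, 1L, 1L, 0L)
    cache$embed <- e
    cache$embed_Tin <- dim(H)[2L]
    H <- e$Y
    at <- attention_forward(p$attn, H)
    cache$attn <- at$caches
    cache$attn_dims <- dim(H)
    H <- at$Y
  } else if (model$kind == "cnn") {
    k <- cfg$kernel_size
    pl <- (k - 1L) %/% 2L
    pr <- k - 1L - pl
    c1 <- conv1d_forward(H, p$conv1$W, p$conv1$b, k, 1L, pl, pr)
    a1 <- apply_activation(c1$Y, act)
    cache$c1 <- c1; cache$a1 <- a1; cache$T1 <- dim(H)[2L]
    pool1 <- avgpool2_forward(a1)
    cache$pool1_dims <- dim(a1)
    c2 <- conv1d_forward(pool1, p$conv2$W, p$conv2$b, k, 1L, pl, pr)
    a2 <- apply_activation(c2$Y, act)
    cache$c2 <- c2; cache$a2 <- a2; cache$T2 <- dim(pool1)[2L]
    cache$pool2_dims <- dim(a2)
    H <- avgpool2_forward(a2)
  } else stopf("unknown model kind '%s'", model$kind)

  cache$feat_dims <- dim(H)
  G <- gap_forward(H)
  cache$G <- G
  logits <- p$head$W %*% G + p$head$b
  list(logits = logits, cache = cache)
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  act <- cfg$activation
  grads <- list()

  grads$head <- list(W = dlogits %*% t(cache$G), b = rowSums(dlogits))
  dG <- crossprod(p$head$W, dlogits)
  dH <- gap_backward(dG, cache$feat_dims)

  if (model$kind %in% c("tcnsa", "tcn")) {
    if (model$kind == "tcnsa") {
      ab <- attention_backward(p$attn, cache$attn, dH)
      grads$attn <- ab$grads
      dH <- ab$dX
    }
    gb <- vector("list", length(p$blocks))
    for (i in rev(seq_along(p$blocks))) {
      bb <- block_backward(p$blocks[[i]], cache$blocks[[i]], dH, act,
                           training = TRUE)
      gb[[i]] <- bb$grads
      dH <- bb$dX
    }
    grads$blocks <- gb
  } else if (model$kind == "sa") {
    ab <- attention_backward(p$attn, cache$attn, dH)
    grads$attn <- ab$grads
    be <- conv1d_backward(ab$dX, p$embed$W, cache$embed, 1L, 1L, 0L,
                          cache$embed_Tin)
    grads$embed <- list(W = be$dW, b = be$db)
  } else if (model$kind == "cnn") {
    k <- cfg$kernel_size
    pl <- (k - 1L) %/% 2L
    da2 <- avgpool2_backward(dH, cache$pool2_dims)
    dc2 <- activation_bwd(da2, cache$a2, act)
    b2 <- conv1d_backward(dc2, p$conv2$W, cache$c2, k, 1L, pl, cache$T2)
    grads$conv2 <- list(W = b2$dW, b = b2$db)
    da1 <- avgpool2_backward(b2$dX, cache$pool1_dims)
    dc1 <- activation_bwd(da1, cache$a1, act)
    b1 <- conv1d_backward(dc1, p$conv1$W, cache$c1, k, 1L, pl, cache$T1)
    grads$conv1 <- list(W = b1$dW, b = b1$db)
  }
  grads
}

# Class probabilities for a [C, T, B] batch (columns of the result are
# samples; rows are classes healthy, EP).
model_probs <- function(model, X) {
  col_softmax(model_forward(model, X, training = FALSE)$logits)
}

# In-place SGD update: every gradient leaf with a matching name is stepped.
sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.list(g)) params[[nm]] <- sgd_step(params[[nm]], g, lr)
    else params[[nm]] <- params[[nm]] - lr * g
  }
  params
}
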