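test_that("receptive_span is d * (k - 1) and rejects bad arguments", {
  expect_identical(receptive_span(3, 2), 3)
  expect_identical(receptive_span(1, 1), 0)
  expect_identical(receptive_span(8, 4), 24)
  expect_error(receptive_span(0, 2), "positive")
  expect_error(receptive_span(2, -1), "positive")
})

test_that("causal dilated convolution matches the direct-summation oracle", {
  # frozen example: kernel [1, 1], d = 1
  expect_equal(causal_dilated_conv(c(1, 2, 3), c(1, 1)), c(1, 3, 5))
  # k = 1 is the identity for a unit kernel
  x <- rnorm(10)
  expect_equal(causal_dilated_conv(x, 1), x)

  set.seed(11)
  for (trial in 1:30) {
    n <- sample(4:32, 1); k <- sample(1:4, 1); d <- sample(1:8, 1)
    x <- rnorm(n); w <- rnorm(k)
    expect_lt(max(abs(causal_dilated_conv(x, w, dilation = d) -
                        oracle_causal_conv(x, w, d))), 1e-10)
  }
  expect_error(causal_dilated_conv(1:5, c(1, 1), dilation = 0), "positive")
})

test_that("causality: outputs never depend on future inputs", {
  set.seed(12)
  cfg <- tiny_model_config(in_length = 24)
  model <- build_baseline("tcn", cfg, seed = 5)
  x <- array(rnorm(2 * 24), c(2, 24, 1))
  base <- eegtcn:::block_forward(model$params$blocks[[1]], x, 1L, "relu", 0, FALSE)$Y
  for (trial in 1:25) {
    t0 <- sample(1:23, 1)
    xp <- x
    future <- (t0 + 1):24
    tf <- future[sample.int(length(future), 1)]
    xp[, tf, 1] <- xp[, tf, 1] + rnorm(2)
    pert <- eegtcn:::block_forward(model$params$blocks[[1]], xp, 1L, "relu", 0, FALSE)$Y
    expect_equal(pert[, 1:t0, 1], base[, 1:t0, 1])
  }
})

test_that("residual block obeys o = activation(x + F(x)) and keeps length", {
  # zero weights make F vanish: identity on non-negative input
  zeros <- function(co, ci, k) list(W = array(0, c(co, ci, k)), b = numeric(co))
  x <- matrix(abs(rnorm(20)), 1)
  expect_equal(residual_block(x, list(conv1 = zeros(1, 1, 2),
                                      conv2 = zeros(1, 1, 2))), x)

  # hand-computed forward pass: 1 channel, T = 3, k = 2, all weights 0.5:
  # conv1([1,2,3]) = [.5, 1.5, 2.5]; conv2 -> [.25, 1, 2]; o = relu(x + F)
  half <- function() list(W = array(0.5, c(1, 1, 2)), b = 0)
  out <- residual_block(matrix(c(1, 2, 3), 1),
                        list(conv1 = half(), conv2 = half()))
  expect_equal(out, matrix(c(1.25, 3, 5), 1))

  # length preservation at the reference segment length, width change via
  # the 1x1 shortcut
  set.seed(13)
  p <- list(conv1 = list(W = array(rnorm(3 * 1 * 4, sd = 0.1), c(3, 1, 4)),
                         b = rnorm(3, sd = 0.1)),
            conv2 = list(W = array(rnorm(3 * 3 * 4, sd = 0.1), c(3, 3, 4)),
                         b = rnorm(3, sd = 0.1)),
            shortcut = list(W = array(rnorm(3), c(3, 1, 1)), b = rnorm(3)))
  y <- residual_block(matrix(rnorm(200), 1), p, dilation = 2)
  expect_identical(dim(y), c(3L, 200L))
})

test_that("self-attention matches Eq.-style brute force and normalizes rows", {
  # length-1 sequence: softmax of a scalar is 1
  sa1 <- self_attention(matrix(2, 1, 3), matrix(1, 1, 3), matrix(c(7, 8, 9), 1))
  expect_equal(sa1$output, matrix(c(7, 8, 9), 1))

  # identical keys: uniform weights; outputs equal the value mean
  Q <- matrix(rnorm(6), 2); M <- matrix(1, 2, 3)[, 1:3]
  M <- rbind(c(1, 2, 3), c(1, 2, 3))
  V <- rbind(c(1, 0, 0), c(0, 1, 0))
  sa2 <- self_attention(Q, M, V)
  expect_equal(sa2$weights, matrix(0.5, 2, 2))
  expect_equal(sa2$output, rbind(colMeans(V), colMeans(V)))

  # identity example against independent arithmetic
  I2 <- diag(2)
  sa3 <- self_attention(I2, I2, I2)
  or <- oracle_attention(I2, I2, I2)
  expect_lt(max(abs(sa3$output - or$output)), 1e-8)

  set.seed(14)
  for (trial in 1:20) {
    n <- sample(2:8, 1); dm <- sample(2:6, 1)
    Q <- matrix(rnorm(n * dm), n); M <- matrix(rnorm(n * dm), n)
    V <- matrix(rnorm(n * dm), n)
    got <- self_attention(Q, M, V)
    or <- oracle_attention(Q, M, V)
    expect_lt(max(abs(got$output - or$output)), 1e-8)
    expect_equal(rowSums(got$weights), rep(1, n), tolerance = 1e-6)
    # permutation equivariance under a joint key/value permutation
    pp <- sample(n)
    got_p <- self_attention(Q, M[pp, , drop = FALSE], V[pp, , drop = FALSE])
    expect_equal(got_p$output, got$output, tolerance = 1e-10)
  }
  expect_error(self_attention(matrix(1, 1, 0), matrix(1, 1, 0), matrix(1, 1, 0)),
               "d_m")
})

test_that("the reference configuration counts 420,662 parameters (0.42 M)", {
  model <- build_model(model_config())
  n <- count_parameters(model)
  expect_identical(n, 420662L)
  expect_identical(round(n / 1e6, 2), 0.42)
  # lone linear map
  expect_identical(count_parameters(list(W = matrix(0, 2, 164),
                                         b = numeric(2))), 330L)
})

test_that("parameter count matches the closed form across a config grid", {
  for (L in 1:3) for (k in c(2, 4)) for (C in c(3, 8)) {
    cfg <- model_config(n_levels = L, kernel_size = k, hidden_width = C,
                        attention_dim = C, in_channels = 5, in_length = 32)
    expect_identical(count_parameters(build_model(cfg, seed = 1)),
                     as.integer(oracle_param_count(cfg)))
  }
})

test_that("the full model emits softmax probability rows of width 2", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 6)
  X <- array(rnorm(2 * 12 * 5), c(2, 12, 5))
  P <- eegtcn:::model_probs(model, X)
  expect_identical(dim(P), c(2L, 5L))
  expect_equal(colSums(P), rep(1, 5), tolerance = 1e-6)
  expect_true(all(is.finite(P)))
})

test_that("baselines build, predict and differ structurally as specified", {
  cfg <- tiny_model_config()
  X <- array(rnorm(2 * 12 * 3), c(2, 12, 3))
  for (kind in c("tcn", "sa", "cnn")) {
    m <- build_baseline(kind, cfg, seed = 7)
    P <- eegtcn:::model_probs(m, X)
    expect_equal(colSums(P), rep(1, 3), tolerance = 1e-6)
    expect_true(all(is.finite(P)))
  }
  # the plain TCN has no attention projections at all
  tcn <- build_baseline("tcn", cfg)
  expect_null(tcn$params$attn)
  # reference-shaped input works for every kind
  cfg19 <- model_config(hidden_width = 8, attention_dim = 8)
  X19 <- array(rnorm(19 * 200 * 2), c(19, 200, 2))
  for (kind in c("tcn", "sa", "cnn")) {
    P <- eegtcn:::model_probs(build_baseline(kind, cfg19, seed = 2), X19)
    expect_true(all(is.finite(P)))
  }
  P <- eegtcn:::model_probs(build_model(cfg19, seed = 2), X19)
  expect_identical(dim(P), c(2L, 2L))
  expect_error(build_baseline("mlp", cfg), "arg")
})

test_that("total receptive field: closed form agrees with a perturbation probe", {
  cfg <- tiny_model_config(n_levels = 2, kernel_size = 3, in_length = 32,
                           in_channels = 1, hidden_width = 4)
  span <- receptive_field(cfg)   # 1 + 2*2*(1 + 2) = 13
  expect_identical(span, 13)
  model <- build_baseline("tcn", cfg, seed = 8)
  fwd <- function(x) {
    H <- array(x, c(1, 32, 1))
    for (i in 1:2)
      H <- eegtcn:::block_forward(model$params$blocks[[i]], H, 2L^(i - 1L),
                                  "relu", 0, FALSE)$Y
    H
  }
  set.seed(15)
  x <- rnorm(32)
  base <- fwd(x)
  t_out <- 32L
  # beyond the receptive field: guaranteed invariance
  for (t_in in 1:(t_out - span)) {
    xp <- x; xp[t_in] <- xp[t_in] + 10
    expect_equal(fwd(xp)[, t_out, 1], base[, t_out, 1])
  }
  # inside: at least one probed position must matter
  changed <- FALSE
  for (t_in in (t_out - span + 1L):t_out) {
    xp <- x; xp[t_in] <- xp[t_in] + 10
    if (any(fwd(xp)[, t_out, 1] != base[, t_out, 1])) changed <- TRUE
  }
  expect_true(changed)
})

test_that("analytic gradients agree with finite differences for all kinds", {
  set.seed(16)
  cfg <- tiny_model_config(in_length = 9)
  X <- array(rnorm(2 * 9 * 3), c(2, 9, 3))
  y <- c(0L, 1L, 1L)
  for (kind in c("tcnsa", "tcn", "sa", "cnn")) {
    model <- if (kind == "tcnsa") build_model(cfg, seed = 4)
             else build_baseline(kind, cfg, seed = 4)
    expect_lt(max_grad_error(model, X, y), 1e-4)
  }
})
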