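# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately naive (loops, direct formulas) so that it
# cannot share bugs with the vectorized implementation under test.

# Direct-summation causal dilated convolution: single output value at time t
# from first principles, zero left padding.
oracle_causal_conv <- function(x, w, d) {
  k <- length(w)
  n <- length(x)
  vapply(seq_len(n), function(t) {
    acc <- 0
    for (j in seq_len(k)) {       # tap j multiplies x[t - (k - j) * d]
      idx <- t - (k - j) * d
      if (idx >= 1) acc <- acc + w[j] * x[idx]
    }
    acc
  }, numeric(1))
}

# Brute-force scaled dot-product attention by explicit loops.
oracle_attention <- function(Q, M, V) {
  n <- nrow(Q); dm <- ncol(M)
  out <- matrix(0, n, ncol(V))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * M[j, ]) / sqrt(dm)
    e <- exp(s - max(s))
    W[i, ] <- e / sum(e)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + W[i, j] * V[j, ]
  }
  list(output = out, weights = W)
}

# Count contiguous runs of `x > threshold` (a robust spike counter: each
# supra-threshold excursion is one peak).
count_peaks <- function(x, threshold) {
  above <- x > threshold
  sum(above & !c(FALSE, above[-length(above)]))
}

# Band power (uV^2/Hz summed over the band) from a raw periodogram.
band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * rate / n
  sel <- f >= lo & f <= hi & f <= rate / 2
  sum(sp[sel])
}

# Frequency of the periodogram maximum.
peak_frequency <- function(x, rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * rate / n
  half <- f > 0 & f <= rate / 2
  f[half][which.max(sp[half])]
}

# Closed-form trainable-parameter count implied by a model configuration
# (weight-norm gains excluded, matching the counting convention).
oracle_param_count <- function(cfg) {
  k <- cfg$kernel_size; C <- cfg$hidden_width
  tot <- 0
  c_in <- cfg$in_channels
  for (i in seq_len(cfg$n_levels)) {
    tot <- tot + (C * c_in * k + C) + (C * C * k + C)      # conv1 + conv2
    if (c_in != C) tot <- tot + (C * c_in + C)             # 1x1 shortcut
    c_in <- C
  }
  tot <- tot + 3 * (C * C + C)                             # Q/K/V projections
  tot + C * cfg$n_classes + cfg$n_classes                  # linear head
}

# AUC as the fraction of concordant positive-negative pairs, ties = 1/2.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# ---- finite-difference gradient checking --------------------------------

nn_loss <- function(model, X, y) {
  P <- eegtcn:::col_softmax(eegtcn:::model_forward(model, X, training = FALSE)$logits)
  eegtcn:::cross_entropy(P, y)
}

# Flatten a gradient tree into (path, values) leaves.
collect_leaves <- function(g, path = character()) {
  leaves <- list()
  nms <- names(g)
  for (i in seq_along(g)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
    if (is.list(g[[i]])) {
      leaves <- c(leaves, collect_leaves(g[[i]], c(path, nm)))
    } else {
      leaves[[length(leaves) + 1L]] <- list(path = c(path, nm), g = g[[i]])
    }
  }
  leaves
}

tree_get <- function(node, keys) { for (k in keys) node <- node[[k]]; node }
tree_set <- function(node, keys, val) {
  if (length(keys) == 0L) return(val)
  k <- keys[[1L]]
  node[[k]] <- tree_set(node[[k]], keys[-1L], val)
  node
}

# Compare analytic gradients with central differences on a random sample of
# coordinates in every gradient leaf; returns the worst relative error.
max_grad_error <- function(model, X, y, n_coords = 3, eps = 1e-6) {
  fw <- eegtcn:::model_forward(model, X, training = FALSE)
  P <- eegtcn:::col_softmax(fw$logits)
  B <- length(y)
  dlog <- P
  dlog[cbind(y + 1L, seq_len(B))] <- dlog[cbind(y + 1L, seq_len(B))] - 1
  dlog <- dlog / B
  grads <- eegtcn:::model_backward(model, fw$cache, dlog)
  worst <- 0
  for (leaf in collect_leaves(grads)) {
    keys <- as.list(leaf$path)
    th <- tree_get(model$params, keys)
    for (j in sample(length(th), min(n_coords, length(th)))) {
      bump <- function(s) {
        t2 <- th; t2[j] <- t2[j] + s
        m2 <- model
        m2$params <- tree_set(m2$params, keys, t2)
        nn_loss(m2, X, y)
      }
      num <- (bump(eps) - bump(-eps)) / (2 * eps)
      rel <- abs(num - leaf$g[j]) / max(1e-6, abs(num) + abs(leaf$g[j]))
      worst <- max(worst, rel)
    }
  }
  worst
}

# ---- shared fixtures -----------------------------------------------------

tiny_model_config <- function(...) {
  defaults <- list(n_levels = 2, kernel_size = 3, hidden_width = 6,
                   attention_dim = 6, in_channels = 2, in_length = 12,
                   dropout = 0)
  args <- utils::modifyList(defaults, list(...))
  if (!("attention_dim" %in% names(list(...))) && "hidden_width" %in% names(list(...)))
    args$attention_dim <- args$hidden_width
  do.call(model_config, args)
}

# A linearly separable toy segment set: class means 0.15 vs 0.85 plus a
# little noise, single channel.
toy_separable_set <- function(n = 12, len = 20, seed = 42) {
  set.seed(seed)
  segs <- lapply(seq_len(n), function(i) {
    ep <- i %% 2L == 0L
    eeg_segment(matrix(stats::rnorm(len, ifelse(ep, 0.85, 0.15), 0.05), 1L),
                subject_id = sprintf("T%02d", i),
                label = if (ep) "EP" else "healthy", normalized = TRUE)
  })
  segment_set(segs)
}

# Small simulated cohort, preprocessed, for split/leakage/experiment tests.
quick_cohort_frame <- function(n_healthy = 21, n_ep = 14) {
  data.frame(subject_id = c(sprintf("H%02d", seq_len(n_healthy)),
                            sprintf("EP%02d", seq_len(n_ep))),
             group = c(rep("healthy", n_healthy), rep("EP", n_ep)),
             stringsAsFactors = FALSE)
}
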