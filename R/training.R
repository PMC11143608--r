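#' Training hyper-parameters
#'
#' Defaults are the reference settings: plain SGD (no momentum), learning
#' rate 0.01, 100 epochs, batch size 12, cross-entropy loss.
#'
#' @param learning_rate SGD step size.
#' @param epochs number of passes over the training set.
#' @param batch_size segments per gradient step; the last short batch of an
#'   epoch is kept.
#' @param seed seed controlling shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 100, batch_size = 12,
                         seed = 1) {
  if (!is_scalar_num(learning_rate) || learning_rate < 0)
    stopf("`learning_rate` must be >= 0")
  if (!is_count(epochs) || !is_count(batch_size))
    stopf("`epochs` and `batch_size` must be positive integers")
  structure(list(learning_rate = as.double(learning_rate),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = "sgd", loss = "cross-entropy",
                 seed = as.integer(seed)),
            class = "train_config")
}

# Largest-remainder apportionment of `total` picks across strata of sizes
# `sizes` (capped per stratum).
apportion <- function(sizes, total) {
  quota <- sizes * total / sum(sizes)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  pmin(as.integer(base), sizes)
}

#' Subject-level train/validation/test split
#'
#' Splits subjects (never segments) into disjoint train, validation and test
#' sets, stratified by group label: the number of test subjects is
#' `ceiling(test_frac * n)` apportioned across strata by largest remainder,
#' and the validation set is drawn the same way from within the training
#' portion. Segment assignment must follow subject assignment, which rules
#' out identity leakage between training and testing.
#'
#' @param cohort recordings list, a data.frame with `subject_id`/`group`
#'   columns, or a named character vector of groups.
#' @param test_frac fraction of subjects held out for testing.
#' @param val_frac fraction of the remaining training subjects used for
#'   validation monitoring.
#' @param seed integer seed.
#' @return Object of class `split_plan` with `train`, `val`, `test`
#'   subject-id vectors.
#' @export
split_subjects <- function(cohort, test_frac = 0.3, val_frac = 0.2, seed = 1) {
  df <- cohort_frame(cohort)
  n <- nrow(df)
  if (n < 3L) stopf("need at least 3 subjects to split")
  if (!is_scalar_num(test_frac) || test_frac <= 0 || test_frac >= 1 ||
      !is_scalar_num(val_frac) || val_frac < 0 || val_frac >= 1)
    stopf("`test_frac` must lie in (0,1) and `val_frac` in [0,1)")

  strata <- split(df$subject_id, df$group)
  sizes <- vapply(strata, length, integer(1))
  n_test <- apportion(sizes, ceiling(test_frac * n))
  if (sum(n_test) >= n) stopf("`test_frac` leaves no training subjects")

  with_seed(seed, {
    test <- character(0); rest <- list()
    for (s in seq_along(strata)) {
      ids <- sample(strata[[s]])
      test <- c(test, ids[seq_len(n_test[s])])
      rest[[s]] <- setdiff(ids, test)
    }
    n_rest <- vapply(rest, length, integer(1))
    n_val <- if (val_frac > 0) apportion(n_rest, ceiling(val_frac * sum(n_rest)))
             else integer(length(rest))
    val <- character(0); train <- character(0)
    for (s in seq_along(rest)) {
      val <- c(val, rest[[s]][seq_len(n_val[s])])
      train <- c(train, setdiff(rest[[s]], val))
    }
    if (length(train) == 0L) stopf("split leaves no training subjects")
    structure(list(train = sort(train), val = sort(val), test = sort(test),
                   seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Construct a fold plan from explicit subject sets
#'
#' @param folds list of character vectors of subject ids; they must be
#'   pairwise disjoint and non-empty.
#' @param seed seed recorded for provenance (NA when hand-built).
#' @return Object of class `fold_plan`.
#' @export
fold_plan <- function(folds, seed = NA_integer_) {
  if (!is.list(folds) || length(folds) < 2L)
    stopf("`folds` must be a list of at least two subject sets")
  ids <- unlist(folds)
  if (anyDuplicated(ids)) stopf("folds must be pairwise disjoint")
  if (any(vapply(folds, length, integer(1)) == 0L)) stopf("empty fold")
  structure(list(folds = lapply(folds, as.character),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d subjects\n",
              length(x$folds), length(unlist(x$folds))))
  for (i in seq_along(x$folds))
    cat(sprintf("  fold %d: %s\n", i, paste(x$folds[[i]], collapse = ", ")))
  invisible(x)
}

#' Group-stratified k-fold partition of subjects
#'
#' Shuffles subjects within each group and deals them round-robin into `k`
#' folds (the second group is dealt in reverse fold order to balance fold
#' sizes), so each fold's healthy:EP composition tracks the cohort's. Every
#' subject lands in exactly one fold.
#'
#' @inheritParams split_subjects
#' @param k number of folds (>= 2, at most the cohort size).
#' @return A [fold_plan()].
#' @export
make_folds <- function(cohort, k = 5, seed = 1) {
  df <- cohort_frame(cohort)
  if (!is_count(k) || k < 2L) stopf("`k` must be an integer >= 2")
  if (k > nrow(df)) stopf("k = %d exceeds the cohort size %d", k, nrow(df))
  with_seed(seed, {
    folds <- replicate(k, character(0), simplify = FALSE)
    strata <- split(df$subject_id, df$group)
    for (s in seq_along(strata)) {
      ids <- sample(strata[[s]])
      pos <- ((seq_along(ids) - 1L) %% k) + 1L
      if (s %% 2L == 0L) pos <- k + 1L - pos   # deal alternate strata backwards
      for (i in seq_along(ids)) folds[[pos[i]]] <- c(folds[[pos[i]]], ids[i])
    }
    fold_plan(lapply(folds, sort), seed = seed)
  })
}

#' Assert that no subject crosses a train/test boundary
#'
#' @param train_ids,test_ids subject-id vectors on the two sides.
#' @return Invisibly TRUE; errors if any subject appears on both sides.
#' @export
assert_no_leakage <- function(train_ids, test_ids) {
  common <- intersect(unique(train_ids), unique(test_ids))
  if (length(common) > 0L)
    stopf("subject-level leakage: %s appear(s) in both train and test",
          paste(common, collapse = ", "))
  invisible(TRUE)
}

# Stratified train/validation split of a cohort frame (no test side):
# ceil(val_frac * n) validation subjects apportioned by largest remainder.
split_train_val <- function(df, val_frac, seed) {
  strata <- split(df$subject_id, df$group)
  sizes <- vapply(strata, length, integer(1))
  n_val <- if (val_frac > 0) apportion(sizes, ceiling(val_frac * nrow(df)))
           else integer(length(strata))
  with_seed(seed, {
    val <- character(0); train <- character(0)
    for (s in seq_along(strata)) {
      ids <- sample(strata[[s]])
      val <- c(val, ids[seq_len(n_val[s])])
      train <- c(train, setdiff(ids, val))
    }
    list(train = sort(train), val = sort(val))
  })
}

#' Subset a segment set to given subjects
#'
#' @param set a [segment_set()].
#' @param ids character vector of subject ids to keep.
#' @return The [segment_set()] restricted to those subjects.
#' @export
subset_subjects <- function(set, ids) {
  keep <- segment_subjects(set) %in% ids
  segment_set(set$segments[keep])
}

cross_entropy <- function(P, y) {
  # P: [2, B] class probabilities, y: 0/1 labels
  idx <- cbind(y + 1L, seq_along(y))
  -mean(log(pmax(P[idx], 1e-12)))
}

#' Train a model by plain SGD with cross-entropy
#'
#' Mini-batch stochastic gradient descent: segments are reshuffled every
#' epoch with the run seed, the last short batch is kept, and there is no
#' momentum, weight decay or early stopping. The validation set is only
#' monitored (never used for weight updates). Runs are bit-reproducible
#' given (model, config) on a fixed platform.
#'
#' @param model an `eeg_model` from [build_model()] or [build_baseline()].
#' @param train_set a non-empty [segment_set()].
#' @param val_set optional [segment_set()] for monitoring.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with `model` (trained) and `history` (data.frame with one
#'   row per epoch: train/val loss and accuracy).
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        config = train_config(), verbose = FALSE) {
  if (!inherits(model, "eeg_model")) stopf("`model` must be an eeg_model")
  if (!inherits(config, "train_config")) stopf("`config` must be a train_config")
  if (!inherits(train_set, "segment_set") || length(train_set) == 0L)
    stopf("`train_set` must be a non-empty segment_set")
  tr <- segments_to_array(train_set)
  va <- if (!is.null(val_set) && length(val_set) > 0L) segments_to_array(val_set)
  n <- dim(tr$x)[3L]
  bs <- config$batch_size
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xb <- tr$x[, , idx, drop = FALSE]
        yb <- tr$y[idx]
        fw <- model_forward(model, Xb, training = TRUE)
        P <- col_softmax(fw$logits)
        B <- length(yb)
        ep_loss <- ep_loss + cross_entropy(P, yb) * B
        ep_correct <- ep_correct + sum((P[2L, ] > P[1L, ]) == (yb == 1L))
        if (config$learning_rate > 0) {
          dlogits <- P
          dlogits[cbind(yb + 1L, seq_len(B))] <-
            dlogits[cbind(yb + 1L, seq_len(B))] - 1
          dlogits <- dlogits / B
          grads <- model_backward(model, fw$cache, dlogits)
          model$params <- sgd_step(model$params, grads, config$learning_rate)
        }
      }
      hist$train_loss[ep] <- ep_loss / n
      hist$train_acc[ep] <- ep_correct / n
      if (!is.null(va)) {
        Pv <- model_probs(model, va$x)
        hist$val_loss[ep] <- cross_entropy(Pv, va$y)
        hist$val_acc[ep] <- mean((Pv[2L, ] > Pv[1L, ]) == (va$y == 1L))
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s", ep,
                        hist$train_loss[ep], hist$train_acc[ep],
                        ifelse(is.na(hist$val_acc[ep]), "-",
                               sprintf("%.3f", hist$val_acc[ep]))))
    }
  })
  list(model = model, history = hist)
}

#' Per-segment class probabilities and hard labels
#'
#' Deterministic evaluation-mode forward pass (dropout off). Results do not
#' depend on how segments are batched.
#'
#' @param model a (trained) `eeg_model`.
#' @param set a [segment_set()].
#' @param batch_size evaluation batch size (no effect on values).
#' @return data.frame with `subject_id`, `label` (truth), `prob_healthy`,
#'   `prob_ep`, and `pred` (argmax: "healthy"/"EP").
#' @export
predict_segments <- function(model, set, batch_size = 64) {
  if (!inherits(set, "segment_set") || length(set) == 0L)
    stopf("`set` must be a non-empty segment_set")
  da <- segments_to_array(set)
  d <- dim(da$x)
  if (d[1L] != model$config$in_channels || d[2L] != model$config$in_length)
    stopf("segments are %d x %d but the model expects %d x %d",
          d[1L], d[2L], model$config$in_channels, model$config$in_length)
  n <- d[3L]
  probs <- matrix(0, 2L, n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[, idx] <- model_probs(model, da$x[, , idx, drop = FALSE])
  }
  data.frame(subject_id = da$subject_id,
             label = ifelse(da$y == 1L, "EP", "healthy"),
             prob_healthy = probs[1L, ], prob_ep = probs[2L, ],
             pred = ifelse(probs[2L, ] > probs[1L, ], "EP", "healthy"),
             stringsAsFactors = FALSE)
}
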