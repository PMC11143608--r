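# Segment-based evaluation suite. The EP (epilepsy) class is the positive
# class throughout: sensitivity is the EP-detection rate, specificity the
# healthy-recognition rate.

as_binary <- function(x, what) {
  if (is.character(x) || is.factor(x)) x <- as.integer(as.character(x) == "EP")
  if (is.logical(x)) x <- as.integer(x)
  if (!all(x %in% c(0L, 1L))) stopf("`%s` must be binary (0/1 or healthy/EP)", what)
  as.integer(x)
}

#' Binary confusion matrix with EP as the positive class
#'
#' @param labels true labels (0/1, logical, or "healthy"/"EP").
#' @param predictions predicted labels, same length and coding.
#' @return Object of class `confusion_matrix` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(labels, predictions) {
  y <- as_binary(labels, "labels")
  p <- as_binary(predictions, "predictions")
  if (length(y) != length(p))
    stopf("labels (%d) and predictions (%d) differ in length", length(y), length(p))
  structure(list(tp = sum(y == 1L & p == 1L), fp = sum(y == 0L & p == 1L),
                 fn = sum(y == 1L & p == 0L), tn = sum(y == 0L & p == 0L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("healthy", "EP"),
                              predicted = c("healthy", "EP")))
  print(m)
  invisible(x)
}

#' The five classification metrics from a confusion matrix
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), precision =
#' tp/(tp+fp), accuracy = (tp+tn)/n, F1 = 2*precision*sensitivity /
#' (precision+sensitivity). A zero denominator yields 0 with a warning
#' rather than NaN.
#'
#' @param cm a [confusion()] result.
#' @return Named numeric vector with `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
metrics_from_confusion <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stopf("`cm` must be a confusion_matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  sens <- safe_div(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  acc <- safe_div(cm$tp + cm$tn, n, "accuracy")
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique EP-class scores, collects
#' (false positive rate, true positive rate) points, and integrates by the
#' trapezoid rule. The resulting AUC equals the probability that a random
#' EP segment scores above a random healthy segment (ties counted 1/2).
#'
#' @param scores EP-class probabilities or scores.
#' @param labels true labels; both classes must be present.
#' @return List with `roc` (data.frame `fpr`, `tpr`, monotone non-decreasing
#'   in both coordinates) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels, "labels")
  if (length(scores) != length(y)) stopf("scores and labels differ in length")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stopf("AUC undefined: need at least one positive and one negative label")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Vertically averaged ROC across folds
#'
#' Interpolates each fold's ROC on a fixed grid of 101 false-positive rates
#' and averages the true-positive rates pointwise; the band is +-1 sample
#' standard deviation. AUC is summarized as mean and sample standard
#' deviation across folds.
#'
#' @param fold_results list of [roc_auc()] results (at least 2).
#' @return List with `fpr` (grid), `tpr_mean`, `tpr_sd`, `auc_mean`,
#'   `auc_sd`.
#' @export
average_roc <- function(fold_results) {
  if (!is.list(fold_results) || length(fold_results) < 2L)
    stopf("need at least two folds to average")
  grid <- seq(0, 1, length.out = 101L)
  tprs <- vapply(fold_results, function(fr) {
    stats::approx(fr$roc$fpr, fr$roc$tpr, xout = grid, ties = max,
                  rule = 2)$y
  }, numeric(101L))
  aucs <- vapply(fold_results, `[[`, numeric(1), "auc")
  list(fpr = grid, tpr_mean = rowMeans(tprs), tpr_sd = apply(tprs, 1L, stats::sd),
       auc_mean = mean(aucs), auc_sd = stats::sd(aucs))
}

#' Per-participant segment-based accuracy
#'
#' For each subject, the fraction of its segments classified correctly,
#' plus how many subjects clear the 0.2 and 0.1 error thresholds (accuracy
#' at least 80% and at least 90%).
#'
#' @param predictions data.frame as returned by [predict_segments()]
#'   (columns `subject_id`, `label`, `pred`).
#' @return List with `accuracy` (named vector, one entry per subject),
#'   `n_above_80`, `n_above_90`, `n_perfect`.
#' @export
per_participant_accuracy <- function(predictions) {
  need <- c("subject_id", "label", "pred")
  if (!all(need %in% names(predictions)))
    stopf("`predictions` needs columns %s", paste(need, collapse = ", "))
  correct <- predictions$label == predictions$pred
  acc <- vapply(split(correct, predictions$subject_id), mean, numeric(1))
  list(accuracy = acc,
       n_above_80 = sum(acc >= 0.8), n_above_90 = sum(acc >= 0.9),
       n_perfect = sum(acc == 1))
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' Without continuity correction: `N (ad - bc)^2 / (r1 r2 c1 c2)`. Used for
#' cohort sex-balance checks. Invariant to transposing the table.
#'
#' @param table 2x2 matrix of counts with positive marginals.
#' @return The chi-square statistic.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0))
    stopf("`table` must be a 2x2 matrix of non-negative counts")
  r <- rowSums(table); cc <- colSums(table)
  if (any(r == 0) || any(cc == 0)) stopf("all marginals must be positive")
  n <- sum(table)
  n * (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])^2 /
    (r[[1]] * r[[2]] * cc[[1]] * cc[[2]])
}

#' Mann-Whitney U statistic
#'
#' Rank-sum statistic with midrank tie handling, reported as
#' `min(U_x, U_y)` as in two-tailed tables. Used for cohort age comparisons.
#'
#' @param x,y numeric samples, both non-empty.
#' @return The U statistic.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stopf("both samples must be non-empty")
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(ux, n1 * n2 - ux)
}
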