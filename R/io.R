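# Readers and writers for the supported plain-text formats, the structured
# experiment configuration, and the end-to-end experiment driver.

#' Read a single-channel benchmark-style ASCII record
#'
#' One numeric sample per line, by convention 23.6 s at 173.61 Hz (4097
#' lines). Non-numeric lines are reported with their line number.
#'
#' @param path file path.
#' @param rate sampling rate to attach (default 173.61 Hz).
#' @param group group label to attach.
#' @param subject_id subject id; defaults to the file name.
#' @return A single-channel [raw_recording()].
#' @export
read_bonn_txt <- function(path, rate = 173.61, group = "healthy",
                          subject_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stopf("format error: %s is empty", path)
  lines <- lines[keep]
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x))
    stopf("format error in %s: non-numeric sample on line %d",
          path, which(is.na(x))[1L])
  raw_recording(matrix(x, nrow = 1L), rate = rate, channels = "EEG",
                subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                group = group)
}

#' Write a single-channel record in benchmark ASCII format
#'
#' Samples are rounded to integers (the format stores one integer per line).
#'
#' @param rec a single-channel [raw_recording()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_bonn_txt <- function(rec, path) {
  if (nrow(rec$signal) != 1L) stopf("benchmark format is single-channel")
  writeLines(as.character(round(rec$signal[1L, ])), path)
  invisible(path)
}

#' Write a multichannel recording as tabular text
#'
#' A self-contained format: `#`-prefixed metadata lines (subject id, group,
#' rate in Hz), then a tab-separated header of channel names, then one row
#' per sample. Values are written with 17 significant digits so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param rec a [raw_recording()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_multichannel <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", rec$subject_id),
               sprintf("# group: %s", rec$group),
               sprintf("# rate: %.10g", rec$rate),
               paste(rec$channels, collapse = "\t")), con)
  m <- t(rec$signal)                      # samples x channels
  cols <- lapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a multichannel recording written by [write_multichannel()]
#'
#' @param path file path.
#' @return A [raw_recording()] with channels ordered as in the file.
#' @export
read_multichannel <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  meta_lines <- head_lines[startsWith(head_lines, "#")]
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  if (is.null(meta$rate))
    stopf("metadata error: %s has no '# rate:' line", path)
  rate <- suppressWarnings(as.numeric(meta$rate))
  if (is.na(rate) || rate <= 0) stopf("metadata error: invalid rate in %s", path)
  dt <- tryCatch(
    data.table::fread(path, skip = length(meta_lines), header = TRUE,
                      sep = "\t", fill = FALSE, data.table = FALSE),
    error = function(e) stopf("format error in %s: %s", path, conditionMessage(e)))
  if (anyNA(dt)) stopf("format error in %s: ragged or non-numeric rows", path)
  raw_recording(t(as.matrix(dt)), rate = rate, channels = names(dt),
                subject_id = meta$subject_id %||% basename(path),
                group = meta$group %||% "healthy")
}

#' Write / read a cohort directory
#'
#' One `<subject_id>.eeg.tsv` file per recording in the
#' [write_multichannel()] format.
#'
#' @param recordings list of [raw_recording()] objects.
#' @param dir directory (created if needed).
#' @return `write_cohort`: the file paths, invisibly. `read_cohort`: the
#'   list of recordings.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(recordings, function(r) {
    p <- file.path(dir, paste0(r$subject_id, ".eeg.tsv"))
    write_multichannel(r, p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.eeg\\.tsv$", full.names = TRUE))
  if (length(paths) == 0L) stopf("no .eeg.tsv recordings found in %s", dir)
  lapply(paths, read_multichannel)
}

#' Assemble an experiment configuration
#'
#' One structured object drives a whole reproducible experiment: simulation,
#' preprocessing, model, training and evaluation settings, all sub-seeds
#' derived deterministically from one master seed.
#'
#' @param simulation a [simulation_config()].
#' @param cohort list with `n_healthy`, `n_ep`, `no_seizure_frac`.
#' @param preprocessing list with `hp`, `lp`, `notch`, `target_rate`,
#'   `window_seconds`.
#' @param model a [model_config()].
#' @param training a [train_config()].
#' @param evaluation list with `k_folds`, `test_frac`, `val_frac`.
#' @param output_dir where [run_experiment()] writes its artifacts.
#' @param seed master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(simulation = simulation_config(),
                              cohort = list(n_healthy = 21, n_ep = 14,
                                            no_seizure_frac = 3 / 14),
                              preprocessing = list(hp = 1.6, lp = 70,
                                                   notch = 50,
                                                   target_rate = 100,
                                                   window_seconds = 2),
                              model = model_config(),
                              training = train_config(),
                              evaluation = list(k_folds = 5, test_frac = 0.3,
                                                val_frac = 0.2),
                              output_dir = tempfile("eegtcn_run_"),
                              seed = 1) {
  cfg <- structure(list(simulation = simulation, cohort = cohort,
                        preprocessing = preprocessing, model = model,
                        training = training, evaluation = evaluation,
                        output_dir = output_dir, seed = as.integer(seed)),
                   class = "experiment_config")
  # master seed drives every stage deterministically
  cfg$simulation$seed <- derive_seed(seed, 1L)
  cfg$training$seed <- derive_seed(seed, 2L)
  cfg
}

#' Write / read an experiment configuration as JSON
#'
#' @param cfg an [experiment_config()].
#' @param path file path.
#' @return `write_experiment_config`: the path, invisibly;
#'   `read_experiment_config`: the restored `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  strip_class <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_class) else x
  plain <- strip_class(cfg)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- raw$simulation
  bb <- sim_args$background_bands
  sim_args$background_bands <- if (is.matrix(bb))
    lapply(seq_len(nrow(bb)), function(i) bb[i, ])
  else if (is.numeric(bb) && length(bb) == 2L) list(bb)
  else if (is.null(bb) || length(bb) == 0L) list()
  else bb
  sim <- do.call(simulation_config, sim_args)
  mod <- do.call(model_config,
                 raw$model[intersect(names(raw$model), names(formals(model_config)))])
  trn <- do.call(train_config,
                 raw$training[intersect(names(raw$training), names(formals(train_config)))])
  cfg <- experiment_config(simulation = sim, cohort = raw$cohort,
                           preprocessing = raw$preprocessing, model = mod,
                           training = trn, evaluation = raw$evaluation,
                           output_dir = raw$output_dir, seed = raw$seed)
  cfg$simulation$seed <- raw$simulation$seed
  cfg$training$seed <- raw$training$seed
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a full cross-validated experiment
#'
#' Simulates (or accepts) a cohort, preprocesses every recording, builds a
#' group-stratified k-fold plan at the subject level, and for each fold
#' trains the requested model kind(s) on the remaining folds (with a
#' subject-level validation split) and evaluates on the held-out fold.
#' Subject-leakage is asserted on every fold. Metrics, ROC points, confusion
#' matrices, per-participant accuracies and training histories are written
#' to `cfg$output_dir` as tabular text; everything is regenerable from the
#' config + seed alone.
#'
#' @param cfg an [experiment_config()].
#' @param models character vector from `c("tcnsa", "tcn", "sa", "cnn")`.
#' @param recordings optional pre-built cohort (list of [raw_recording()]);
#'   when NULL the simulator is used.
#' @param verbose print progress.
#' @return Object of class `metrics_report`: per-model list with per-fold
#'   metrics, mean/sd aggregates, averaged ROC with AUC, confusion
#'   matrices, and per-participant accuracies.
#' @export
run_experiment <- function(cfg, models = "tcnsa", recordings = NULL,
                           verbose = FALSE) {
  if (!inherits(cfg, "experiment_config")) stopf("`cfg` must be an experiment_config")
  stopifnot(all(models %in% c("tcnsa", "tcn", "sa", "cnn")))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", what, conditionMessage(e)))
  }

  recs <- stage("simulate", {
    recordings %||% simulate_cohort(cfg$cohort$n_healthy, cfg$cohort$n_ep,
                                    cfg$simulation,
                                    no_seizure_frac = cfg$cohort$no_seizure_frac %||% 3 / 14)
  })

  pp <- cfg$preprocessing
  sets <- stage("preprocess", lapply(recs, preprocess_recording,
                                     hp = pp$hp, lp = pp$lp, notch = pp$notch,
                                     target_rate = pp$target_rate,
                                     window_seconds = pp$window_seconds))
  all_segments <- do.call(c, sets)
  d <- dim(all_segments$segments[[1L]]$values)
  mcfg <- cfg$model
  mcfg$in_channels <- d[1L]
  mcfg$in_length <- d[2L]

  cohort_df <- cohort_frame(recs)
  k <- cfg$evaluation$k_folds
  plan <- stage("folds", make_folds(cohort_df, k = k,
                                    seed = derive_seed(cfg$seed, 3L)))

  report <- list()
  for (kind in models) {
    fold_metrics <- list(); fold_rocs <- list(); fold_conf <- list()
    preds_all <- list(); histories <- list()
    for (f in seq_len(k)) {
      test_ids <- plan$folds[[f]]
      rest_ids <- setdiff(cohort_df$subject_id, test_ids)
      assert_no_leakage(rest_ids, test_ids)
      rest_df <- cohort_df[cohort_df$subject_id %in% rest_ids, ]
      vs <- split_train_val(rest_df, cfg$evaluation$val_frac,
                            seed = derive_seed(cfg$seed, 100L + f))
      train_ids <- vs$train
      val_ids <- vs$val
      assert_no_leakage(c(train_ids, val_ids), test_ids)

      tr_set <- subset_subjects(all_segments, train_ids)
      va_set <- subset_subjects(all_segments, val_ids)
      te_set <- subset_subjects(all_segments, test_ids)

      model <- if (kind == "tcnsa")
        build_model(mcfg, seed = derive_seed(cfg$seed, 200L + f))
      else build_baseline(kind, mcfg, seed = derive_seed(cfg$seed, 200L + f))
      tcfg <- cfg$training
      tcfg$seed <- derive_seed(cfg$training$seed, f)
      if (verbose) message(sprintf("[%s] fold %d/%d: train %d / val %d / test %d segments",
                                   kind, f, k, length(tr_set), length(va_set),
                                   length(te_set)))
      fit <- stage("train", train_model(model, tr_set, va_set, tcfg))
      preds <- stage("evaluate", predict_segments(fit$model, te_set))
      cm <- confusion(preds$label, preds$pred)
      fold_metrics[[f]] <- metrics_from_confusion(cm)
      fold_rocs[[f]] <- roc_auc(preds$prob_ep, preds$label)
      fold_conf[[f]] <- cm
      preds_all[[f]] <- preds
      histories[[f]] <- fit$history
    }
    mm <- do.call(rbind, fold_metrics)
    preds_pooled <- do.call(rbind, preds_all)
    avg <- if (k >= 2) average_roc(fold_rocs) else NULL
    per_part <- per_participant_accuracy(preds_pooled)
    report[[kind]] <- list(
      per_fold = data.frame(fold = seq_len(k), mm),
      mean = colMeans(mm), sd = apply(mm, 2L, stats::sd),
      rocs = fold_rocs, average_roc = avg,
      confusion = fold_conf, per_participant = per_part,
      histories = histories, predictions = preds_pooled)

    out <- file.path(cfg$output_dir, kind)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_tsv(report[[kind]]$per_fold, file.path(out, "metrics_per_fold.tsv"))
    write_tsv(data.frame(metric = colnames(mm), mean = colMeans(mm),
                         sd = apply(mm, 2L, stats::sd)),
              file.path(out, "metrics_summary.tsv"))
    for (f in seq_len(k)) {
      write_tsv(fold_rocs[[f]]$roc, file.path(out, sprintf("roc_fold%d.tsv", f)))
      write_tsv(histories[[f]], file.path(out, sprintf("history_fold%d.tsv", f)))
      cmf <- fold_conf[[f]]
      write_tsv(data.frame(tp = cmf$tp, fp = cmf$fp, fn = cmf$fn, tn = cmf$tn),
                file.path(out, sprintf("confusion_fold%d.tsv", f)))
    }
    if (!is.null(avg))
      write_tsv(data.frame(fpr = avg$fpr, tpr_mean = avg$tpr_mean,
                           tpr_sd = avg$tpr_sd),
                file.path(out, "roc_mean.tsv"))
    write_tsv(data.frame(subject_id = names(per_part$accuracy),
                         accuracy = unname(per_part$accuracy)),
              file.path(out, "per_participant.tsv"))
  }

  write_experiment_config(cfg, file.path(cfg$output_dir, "config.json"))
  writeLines(c(sprintf("master_seed: %d", cfg$seed),
               sprintf("simulation_seed: %d", cfg$simulation$seed),
               sprintf("training_seed: %d", cfg$training$seed),
               sprintf("config_hash: %08x",
                       sum(utf8ToInt(paste(utils::capture.output(utils::str(cfg)),
                                           collapse = "")))),
               sprintf("models: %s", paste(models, collapse = ",")),
               sprintf("elapsed_s: %.1f", as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs")))),
             file.path(cfg$output_dir, "log.txt"))
  structure(report, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (kind in names(x)) {
    cat(sprintf("== %s ==\n", kind))
    m <- x[[kind]]$mean; s <- x[[kind]]$sd
    for (nm in names(m))
      cat(sprintf("  %-12s %6.2f%% +- %.2f\n", nm, 100 * m[[nm]], 100 * s[[nm]]))
    if (!is.null(x[[kind]]$average_roc))
      cat(sprintf("  %-12s %6.3f  +- %.3f\n", "AUC",
                  x[[kind]]$average_roc$auc_mean, x[[kind]]$average_roc$auc_sd))
  }
  invisible(x)
}
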