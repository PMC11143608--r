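#' Standard 10-20 channel names
#'
#' The 19 recording electrodes of the international 10-20 system in
#' conventional order, as used on clinical EEG instruments.
#'
#' @return Character vector of length 19.
#' @export
ten_twenty_channels <- function() {
  c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

default_channel_names <- function(n) {
  if (n == 19L) ten_twenty_channels() else paste0("CH", seq_len(n))
}

#' Construct a raw EEG recording
#'
#' A `raw_recording` is one subject's continuous multichannel EEG: a
#' channels-by-samples numeric matrix in microvolts, its sampling rate, the
#' channel names, a subject identifier and a group label (`"healthy"` or
#' `"EP"` for epilepsy). An optional event table (onset/duration in seconds)
#' records injected or annotated epileptiform discharges.
#'
#' @param signal numeric matrix, channels x samples (a vector is treated as a
#'   single channel), amplitudes in microvolts.
#' @param rate sampling rate in Hz, positive scalar.
#' @param channels character vector of channel names, one per row of
#'   `signal`. Defaults to the 10-20 names for 19 channels.
#' @param subject_id subject identifier string.
#' @param group `"healthy"` or `"EP"`.
#' @param events optional data.frame with columns `onset`, `duration`
#'   (seconds) and `type`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, rate, channels = NULL, subject_id = "S01",
                          group = c("healthy", "EP"), events = NULL) {
  if (is.vector(signal) && is.numeric(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stopf("`signal` must be a numeric channels x samples matrix")
  group <- match.arg(group)
  if (!is_scalar_num(rate) || rate <= 0)
    stopf("`rate` must be a positive sampling rate in Hz")
  if (is.null(channels)) channels <- default_channel_names(nrow(signal))
  if (length(channels) != nrow(signal))
    stopf("%d channel names supplied for %d signal rows",
          length(channels), nrow(signal))
  structure(
    list(subject_id = as.character(subject_id), group = group,
         rate = as.double(rate), channels = as.character(channels),
         signal = signal, events = events),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s [%s]: %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$group, nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate))
  if (!is.null(x$events) && nrow(x$events) > 0L)
    cat(sprintf("  %d epileptiform event(s), total %.1f s\n",
                nrow(x$events), sum(x$events$duration)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signal)
rec_duration <- function(rec) ncol(rec$signal) / rec$rate

#' Fixed-length EEG segment
#'
#' One non-overlapping analysis window cut from a preprocessed recording.
#' Carries the subject identity and group label so that all downstream
#' splitting can stay subject-wise.
#'
#' @param values numeric matrix channels x window samples.
#' @param subject_id subject identifier.
#' @param label `"healthy"` or `"EP"`.
#' @param normalized logical; TRUE once min-max scaled to `[0, 1]`.
#' @return Object of class `eeg_segment`.
#' @export
eeg_segment <- function(values, subject_id, label = c("healthy", "EP"),
                        normalized = FALSE) {
  label <- match.arg(label)
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric channels x samples matrix")
  structure(list(values = values, subject_id = as.character(subject_id),
                 label = label, normalized = isTRUE(normalized)),
            class = "eeg_segment")
}

#' Ordered collection of segments
#'
#' @param segments list of [eeg_segment()] objects, time-ordered within each
#'   recording.
#' @return Object of class `segment_set`.
#' @export
segment_set <- function(segments = list()) {
  if (!all(vapply(segments, inherits, logical(1), "eeg_segment")))
    stopf("all elements must be eeg_segment objects")
  structure(list(segments = segments), class = "segment_set")
}

#' @export
length.segment_set <- function(x) length(x$segments)

#' @export
c.segment_set <- function(...) {
  sets <- list(...)
  segment_set(do.call(c, lapply(sets, function(s) s$segments)))
}

#' @export
print.segment_set <- function(x, ...) {
  n <- length(x$segments)
  if (n == 0L) { cat("<segment_set> empty\n"); return(invisible(x)) }
  d <- dim(x$segments[[1L]]$values)
  subs <- subject_index(x)
  cat(sprintf("<segment_set> %d segment(s) of %d x %d from %d subject(s)\n",
              n, d[1L], d[2L], length(subs)))
  invisible(x)
}

#' Map subject ids to segment positions
#'
#' @param set a [segment_set()].
#' @return Named list: for each subject id, the integer positions of its
#'   segments within the set.
#' @export
subject_index <- function(set) {
  ids <- vapply(set$segments, function(s) s$subject_id, character(1))
  split(seq_along(ids), ids)
}

segment_subjects <- function(set)
  vapply(set$segments, function(s) s$subject_id, character(1))

segment_labels <- function(set)
  vapply(set$segments, function(s) s$label, character(1))

# Stack a segment set into a [channels, time, n] array plus labels/ids.
segments_to_array <- function(set) {
  n <- length(set$segments)
  if (n == 0L) stopf("empty segment set")
  d <- dim(set$segments[[1L]]$values)
  X <- array(0, dim = c(d[1L], d[2L], n))
  for (i in seq_len(n)) {
    v <- set$segments[[i]]$values
    if (!all(dim(v) == d)) stopf("segments have inconsistent shapes")
    X[, , i] <- v
  }
  list(x = X,
       y = as.integer(segment_labels(set) == "EP"),
       subject_id = segment_subjects(set))
}

# data.frame(subject_id, group) view of a cohort given as recordings,
# a data.frame, or a named character vector of groups.
cohort_frame <- function(cohort) {
  if (is.data.frame(cohort)) {
    if (!all(c("subject_id", "group") %in% names(cohort)))
      stopf("cohort data.frame needs columns `subject_id` and `group`")
    df <- cohort[, c("subject_id", "group")]
  } else if (is.list(cohort) && all(vapply(cohort, inherits, logical(1), "raw_recording"))) {
    df <- data.frame(subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
                     group = vapply(cohort, `[[`, character(1), "group"),
                     stringsAsFactors = FALSE)
  } else if (is.character(cohort) && !is.null(names(cohort))) {
    df <- data.frame(subject_id = names(cohort), group = unname(cohort),
                     stringsAsFactors = FALSE)
  } else {
    stopf("cannot interpret `cohort`; supply recordings, a data.frame or a named group vector")
  }
  if (anyDuplicated(df$subject_id)) stopf("duplicate subject ids in cohort")
  if (!all(df$group %in% c("healthy", "EP"))) stopf("groups must be 'healthy' or 'EP'")
  df
}
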