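# Preprocessing: zero-phase filtering, anti-aliased downsampling,
# non-overlapping segmentation, per-channel min-max normalization.
#
# No DSP package is assumed: filters apply the Butterworth magnitude
# response of the stated order directly to the FFT of each channel (a
# zero-phase filter by construction), and resampling truncates the spectrum
# and inverts at the new length (inherently anti-aliased). Both are
# bit-deterministic.

# Combined zero-phase gain at folded frequency f (Hz): 4th-order Butterworth
# high-pass, 4th-order low-pass, 2nd-order band-stop for mains.
butter_gain <- function(f, hp, lp, notch) {
  g <- rep(1, length(f))
  if (!is.null(hp) && hp > 0)
    g <- g * ifelse(f <= 0, 0, 1 / sqrt(1 + (hp / pmax(f, 1e-12))^8))
  if (!is.null(lp) && lp > 0)
    g <- g * 1 / sqrt(1 + (f / lp)^8)
  if (!is.null(notch) && notch > 0) {
    nl <- notch - 2; nh <- notch + 2          # 48-52 Hz stop band for 50 Hz mains
    f0sq <- nl * nh; bw <- nh - nl
    r <- (f * bw) / (f^2 - f0sq)
    r[!is.finite(r)] <- Inf                   # exactly on the notch centre
    g <- g * 1 / sqrt(1 + r^4)
  }
  g
}

# Apply a real, zero-phase gain curve to one channel via the FFT.
fft_filter_channel <- function(x, rate, hp, lp, notch) {
  n <- length(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * rate / n
  g <- butter_gain(f, hp, lp, notch)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

#' Band-limit a recording
#'
#' Zero-phase high-pass, low-pass and mains band-stop filtering at the
#' recording's native rate. Defaults follow standard clinical EEG practice:
#' 1.6 Hz high-pass (drift removal), 70 Hz low-pass, and a 48-52 Hz 2nd-order
#' band-stop against 50 Hz power-line interference. Filtering happens before
#' any downsampling so the 70 Hz cutoff is meaningful.
#'
#' @param rec a [raw_recording()].
#' @param hp high-pass cutoff in Hz (NULL to skip).
#' @param lp low-pass cutoff in Hz (NULL to skip); must be below the Nyquist
#'   frequency of `rec`.
#' @param notch mains frequency in Hz (NULL to skip).
#' @return The filtered [raw_recording()], same shape and rate.
#' @export
apply_filters <- function(rec, hp = 1.6, lp = 70, notch = 50) {
  if (!inherits(rec, "raw_recording")) stopf("`rec` must be a raw_recording")
  if (!is.null(lp) && lp >= rec$rate / 2)
    stopf("low-pass cutoff %g Hz is not below the Nyquist frequency %g Hz",
          lp, rec$rate / 2)
  sig <- rec$signal
  for (ch in seq_len(nrow(sig)))
    sig[ch, ] <- fft_filter_channel(sig[ch, ], rec$rate, hp, lp, notch)
  out <- rec
  out$signal <- sig
  out
}

# FFT-based resampling of one channel to m samples (m <= n).
fft_resample_channel <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  Y[1L] <- X[1L]
  J <- floor((m - 1) / 2)
  if (J >= 1L) {
    j <- seq_len(J)
    Y[1L + j] <- X[1L + j]
    Y[m + 1L - j] <- Conj(X[1L + j])
  }
  if (m %% 2L == 0L) Y[m / 2 + 1L] <- Re(X[m / 2 + 1L])
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Downsample a recording
#'
#' Anti-aliased downsampling to `target_rate`. The output length is the
#' nominal-duration sample count, `round(n * target_rate / rate)`: a 2 s
#' recording at 500 Hz maps to exactly 200 samples and a 4097-sample record
#' at 173.61 Hz (nominally 23.6 s) to exactly 2360 samples at 100 Hz.
#' Upsampling is not supported.
#'
#' @param rec a [raw_recording()].
#' @param target_rate new sampling rate in Hz, at most `rec$rate`.
#' @return The resampled [raw_recording()].
#' @export
resample_to <- function(rec, target_rate = 100) {
  if (!inherits(rec, "raw_recording")) stopf("`rec` must be a raw_recording")
  if (!is_scalar_num(target_rate) || target_rate <= 0)
    stopf("`target_rate` must be > 0")
  if (target_rate > rec$rate)
    stopf("upsampling not supported: target %g Hz > native %g Hz",
          target_rate, rec$rate)
  n <- n_samples(rec)
  m <- floor(n * target_rate / rec$rate + 0.5)
  if (m < 1L) stopf("recording too short to resample to %g Hz", target_rate)
  sig <- matrix(0, nrow = nrow(rec$signal), ncol = m)
  for (ch in seq_len(nrow(sig)))
    sig[ch, ] <- fft_resample_channel(rec$signal[ch, ], m)
  raw_recording(sig, rate = target_rate, channels = rec$channels,
                subject_id = rec$subject_id, group = rec$group,
                events = rec$events)
}

#' Cut a recording into non-overlapping fixed-length segments
#'
#' Slides a non-overlapping window of `window_seconds` over the recording;
#' the trailing remainder shorter than one window is discarded. Every
#' segment inherits the subject id and group label. A window longer than the
#' recording yields an empty set.
#'
#' @param rec a (preprocessed) [raw_recording()].
#' @param window_seconds window length in seconds (default 2, i.e. 200
#'   samples at 100 Hz).
#' @return A [segment_set()].
#' @export
segment_recording <- function(rec, window_seconds = 2) {
  if (!inherits(rec, "raw_recording")) stopf("`rec` must be a raw_recording")
  if (!is_scalar_num(window_seconds) || window_seconds <= 0)
    stopf("`window_seconds` must be > 0")
  w <- round(window_seconds * rec$rate)
  n <- n_samples(rec)
  k <- floor(n / w)
  segs <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * w + 1L):(i * w)
    segs[[i]] <- eeg_segment(rec$signal[, idx, drop = FALSE],
                             subject_id = rec$subject_id, label = rec$group)
  }
  segment_set(segs)
}

#' Min-max normalize a segment to the unit interval
#'
#' Per channel, within the segment: `z = (x - min) / (max - min)`, so every
#' value lies in `[0, 1]`. A constant channel (max = min) maps to zeros.
#' Idempotent on non-constant channels.
#'
#' @param seg an [eeg_segment()].
#' @return The normalized [eeg_segment()] with the `normalized` flag set.
#' @export
normalize_segment <- function(seg) {
  if (!inherits(seg, "eeg_segment")) stopf("`seg` must be an eeg_segment")
  v <- seg$values
  lo <- apply(v, 1L, min)
  hi <- apply(v, 1L, max)
  rng <- hi - lo
  for (ch in seq_len(nrow(v)))
    v[ch, ] <- if (rng[ch] == 0) 0 else (v[ch, ] - lo[ch]) / rng[ch]
  eeg_segment(v, subject_id = seg$subject_id, label = seg$label,
              normalized = TRUE)
}

#' @rdname normalize_segment
#' @param set a [segment_set()].
#' @export
normalize_segments <- function(set) {
  if (!inherits(set, "segment_set")) stopf("`set` must be a segment_set")
  segment_set(lapply(set$segments, normalize_segment))
}

#' Full preprocessing pipeline for one recording
#'
#' Filter at the native rate, downsample, cut into non-overlapping windows,
#' and min-max normalize each window: the standard path from a raw recording
#' to model-ready segments (19 x 200 for the clinical configuration, 1 x 100
#' for the single-channel benchmark configuration).
#'
#' @inheritParams apply_filters
#' @inheritParams resample_to
#' @inheritParams segment_recording
#' @return A normalized [segment_set()].
#' @export
preprocess_recording <- function(rec, hp = 1.6, lp = 70, notch = 50,
                                 target_rate = 100, window_seconds = 2) {
  rec <- apply_filters(rec, hp = hp, lp = lp, notch = notch)
  rec <- resample_to(rec, target_rate = target_rate)
  normalize_segments(segment_recording(rec, window_seconds = window_seconds))
}
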