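#' Configuration for the synthetic EEG simulator
#'
#' Describes the surrogate recordings the simulator produces. Defaults
#' emulate a 19-channel, 500 Hz pediatric resting-state recording whose
#' epileptiform content mirrors a curated clinical fragment set: in recordings
#' from the epilepsy group, interictal 3 Hz spike-and-wave discharges are
#' dense (near-continuous), because the clinical fragments this surrogate
#' stands in for were selected to contain abnormal discharges.
#'
#' @param n_channels number of channels (19 clinical, 1 benchmark-style).
#' @param rate sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param background_bands list of `c(center_hz, amplitude_uv)` pairs for
#'   sinusoidal background rhythms (default: a 9 Hz posterior-dominant rhythm
#'   at 30 uV and a weak 18 Hz beta component).
#' @param noise_exponent slope of the 1/f^a background noise spectrum.
#' @param noise_scale RMS amplitude (uV) of the 1/f noise component.
#' @param event_rate epileptiform discharge bursts per minute (default 18,
#'   which with 2-4 s bursts makes discharges near-continuous).
#' @param event_freq spike-and-wave repetition frequency in Hz (classically 3).
#' @param event_amplitude spike peak amplitude in uV.
#' @param seed integer seed; identical config + seed gives bit-identical data.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_channels = 19, rate = 500, duration = 120,
                              background_bands = list(c(9, 30), c(18, 8)),
                              noise_exponent = 1, noise_scale = 15,
                              event_rate = 18, event_freq = 3,
                              event_amplitude = 200, seed = 1) {
  if (!is_count(n_channels)) stopf("`n_channels` must be a positive integer")
  if (!is_scalar_num(rate) || rate <= 0) stopf("`rate` must be > 0")
  if (!is_scalar_num(duration) || duration <= 0) stopf("`duration` must be > 0")
  if (!is_scalar_num(event_rate) || event_rate < 0) stopf("`event_rate` must be >= 0")
  if (!is_scalar_num(event_freq) || event_freq <= 0) stopf("`event_freq` must be > 0")
  if (!is_scalar_num(event_amplitude) || event_amplitude < 0)
    stopf("`event_amplitude` must be >= 0")
  if (!is_scalar_num(noise_scale) || noise_scale < 0) stopf("`noise_scale` must be >= 0")
  bands <- lapply(background_bands, function(b) {
    if (length(b) != 2L || !is.numeric(b) || b[1L] <= 0 || b[2L] < 0)
      stopf("each background band must be c(center_hz > 0, amplitude_uv >= 0)")
    as.double(b)
  })
  structure(list(n_channels = as.integer(n_channels), rate = as.double(rate),
                 duration = as.double(duration), background_bands = bands,
                 noise_exponent = as.double(noise_exponent),
                 noise_scale = as.double(noise_scale),
                 event_rate = as.double(event_rate),
                 event_freq = as.double(event_freq),
                 event_amplitude = as.double(event_amplitude),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# One channel of 1/f^a Gaussian noise with the requested RMS, via spectral
# shaping of white noise.
powerlaw_noise <- function(n, exponent, rms) {
  if (rms <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)                      # folded (two-sided) frequency index
  shape <- ifelse(f == 0, 0, f^(-exponent / 2))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y * (rms / s)
}

#' Simulate healthy background EEG
#'
#' Generates one surrogate recording as the sum of 1/f^a Gaussian noise and
#' sinusoidal band components with random phase per channel. The result is
#' labelled `healthy` and is bit-identical for identical config + seed.
#'
#' @param config a [simulation_config()].
#' @param subject_id subject identifier for the recording.
#' @return A [raw_recording()] with `group = "healthy"`.
#' @export
simulate_background <- function(config, subject_id = "H01") {
  if (!inherits(config, "simulation_config")) stopf("`config` must be a simulation_config")
  n <- floor(config$duration * config$rate)
  if (n < 1L) stopf("duration x rate must yield at least one sample")
  tt <- (seq_len(n) - 1L) / config$rate
  sig <- matrix(0, nrow = config$n_channels, ncol = n)
  with_seed(config$seed, {
    for (ch in seq_len(config$n_channels)) {
      x <- powerlaw_noise(n, config$noise_exponent, config$noise_scale)
      for (b in config$background_bands) {
        phase <- stats::runif(1, 0, 2 * pi)
        x <- x + b[2L] * sin(2 * pi * b[1L] * tt + phase)
      }
      sig[ch, ] <- x
    }
  })
  raw_recording(sig, rate = config$rate, subject_id = subject_id,
                group = "healthy")
}

# One spike-and-wave cycle at the given rate: a biphasic sharp transient
# (~60 ms, positive lobe then a shallower negative lobe) followed by a
# half-sine slow wave filling the rest of the cycle. Peak of the spike is
# `amplitude`; the slow-wave peak is 0.25 * amplitude so that spike maxima
# are cleanly separable from wave maxima.
spike_wave_cycle <- function(rate, freq, amplitude) {
  n <- max(2L, round(rate / freq))
  cyc <- numeric(n)
  ns <- min(n, max(2L, round(0.06 * rate)))
  u <- (seq_len(ns) - 0.5) / ns
  spike <- sin(2 * pi * u)
  spike[spike < 0] <- 0.6 * spike[spike < 0]
  cyc[seq_len(ns)] <- amplitude * spike
  nw <- n - ns
  if (nw > 0L) {
    v <- (seq_len(nw) - 0.5) / nw
    cyc[ns + seq_len(nw)] <- 0.25 * amplitude * sin(pi * v)
  }
  cyc
}

#' Inject spike-and-wave discharges into a recording
#'
#' Adds stereotyped spike-and-wave bursts (sharp ~60 ms transient followed by
#' a slow half-sine wave, repeating at `config$event_freq`) at the requested
#' onsets. Events share timing across channels; each channel receives the
#' template scaled by a per-subject factor drawn once (uniform on 0.7-1.3).
#' Samples outside events are untouched. With a non-empty event list the
#' returned recording is labelled `EP`; an empty list returns the input
#' unchanged.
#'
#' @param rec a [raw_recording()].
#' @param events list of `c(onset_s, duration_s)` pairs, or a data.frame with
#'   columns `onset` and `duration` (and optionally `type`).
#' @param config a [simulation_config()] supplying `event_freq`,
#'   `event_amplitude` and the seed for the per-channel scales.
#' @param amplitude_scale multiplier on `config$event_amplitude` (ictal
#'   bursts use > 1).
#' @param type event label stored in the recording's event table.
#' @return A [raw_recording()]; `group = "EP"` iff at least one event was
#'   injected.
#' @export
inject_spike_wave <- function(rec, events, config, amplitude_scale = 1,
                              type = "interictal") {
  if (!inherits(rec, "raw_recording")) stopf("`rec` must be a raw_recording")
  if (!inherits(config, "simulation_config")) stopf("`config` must be a simulation_config")
  ev <- normalize_events(events)
  if (nrow(ev) == 0L) return(rec)
  dur <- rec_duration(rec)
  bad <- ev$onset < 0 | ev$duration <= 0 | (ev$onset + ev$duration) > dur + 1e-9
  if (any(bad))
    stopf("event at onset %.3f s (duration %.3f s) lies outside the %.3f s recording",
          ev$onset[which(bad)[1L]], ev$duration[which(bad)[1L]], dur)

  n_ch <- nrow(rec$signal)
  scales <- with_seed(derive_seed(config$seed, 991L), stats::runif(n_ch, 0.7, 1.3))
  cyc <- spike_wave_cycle(rec$rate, config$event_freq,
                          config$event_amplitude * amplitude_scale)
  sig <- rec$signal
  n <- ncol(sig)
  for (i in seq_len(nrow(ev))) {
    n_cycles <- floor(ev$duration[i] * config$event_freq)
    if (n_cycles < 1L) next
    burst <- rep(cyc, n_cycles)
    start <- floor(ev$onset[i] * rec$rate) + 1L
    idx <- start:min(n, start + length(burst) - 1L)
    sig[, idx] <- sig[, idx] + outer(scales, burst[seq_along(idx)])
  }
  ev$type <- if ("type" %in% names(ev)) ev$type else type
  all_ev <- rbind(rec$events, ev[, c("onset", "duration", "type")])
  raw_recording(sig, rate = rec$rate, channels = rec$channels,
                subject_id = rec$subject_id, group = "EP", events = all_ev)
}

normalize_events <- function(events) {
  if (is.null(events) || (is.list(events) && length(events) == 0L))
    return(data.frame(onset = numeric(0), duration = numeric(0)))
  if (is.data.frame(events)) {
    if (!all(c("onset", "duration") %in% names(events)))
      stopf("event data.frame needs columns `onset` and `duration`")
    return(events)
  }
  if (is.numeric(events) && length(events) == 2L) events <- list(events)
  if (!is.list(events)) stopf("`events` must be a list of c(onset, duration) pairs")
  data.frame(onset = vapply(events, `[[`, numeric(1), 1L),
             duration = vapply(events, `[[`, numeric(1), 2L))
}

# Near-contiguous interictal discharge schedule: bursts of 2-4 s separated by
# exponential gaps whose mean is set so that the long-run burst count matches
# `event_rate` per minute. At least one event is always scheduled.
draw_event_schedule <- function(duration, event_rate, seed) {
  mean_dur <- 3
  gap_mean <- max(0.05, 60 / max(event_rate, 1e-6) - mean_dur)
  with_seed(seed, {
    onsets <- numeric(0); durs <- numeric(0)
    t <- stats::rexp(1, 1 / gap_mean)
    repeat {
      d <- stats::runif(1, 2, 4)
      if (t + d > duration) break
      onsets <- c(onsets, t); durs <- c(durs, d)
      t <- t + d + stats::rexp(1, 1 / gap_mean)
    }
    if (length(onsets) == 0L && duration > 2.5) {
      onsets <- duration / 4; durs <- min(3, duration / 2)
    }
    data.frame(onset = onsets, duration = durs)
  })
}

#' Simulate a cohort of healthy and epilepsy recordings
#'
#' Produces `n_healthy` background-only recordings and `n_ep` recordings with
#' dense interictal spike-and-wave discharges. A fraction of the epilepsy
#' subjects (default 3/14, mirroring a cohort in which three children had no
#' seizures during recording) receive no ictal bursts; the remainder also get
#' one or two longer, higher-amplitude ictal bursts.
#'
#' @param n_healthy,n_ep subject counts; their sum must be at least 1.
#' @param config a [simulation_config()]; per-subject seeds are derived from
#'   `config$seed`.
#' @param no_seizure_frac fraction of EP subjects with interictal events only.
#' @return List of [raw_recording()] objects with distinct subject ids.
#' @export
simulate_cohort <- function(n_healthy, n_ep, config = simulation_config(),
                            no_seizure_frac = 3 / 14) {
  if (!is.numeric(n_healthy) || !is.numeric(n_ep) || n_healthy < 0 || n_ep < 0 ||
      n_healthy + n_ep < 1)
    stopf("cohort must contain at least one subject")
  n_healthy <- as.integer(n_healthy); n_ep <- as.integer(n_ep)
  recs <- vector("list", n_healthy + n_ep)
  i <- 0L
  for (h in seq_len(n_healthy)) {
    i <- i + 1L
    cfg_h <- config
    cfg_h$seed <- derive_seed(config$seed, i)
    recs[[i]] <- simulate_background(cfg_h, subject_id = sprintf("H%02d", h))
  }
  n_no_ictal <- round(no_seizure_frac * n_ep)
  no_ictal <- if (n_ep > 0L)
    with_seed(derive_seed(config$seed, 577L), sample(n_ep, n_no_ictal)) else integer(0)
  for (e in seq_len(n_ep)) {
    i <- i + 1L
    cfg_e <- config
    cfg_e$seed <- derive_seed(config$seed, i)
    rec <- simulate_background(cfg_e, subject_id = sprintf("EP%02d", e))
    sched <- draw_event_schedule(config$duration, config$event_rate,
                                 derive_seed(cfg_e$seed, 13L))
    rec <- inject_spike_wave(rec, sched, cfg_e)
    if (!(e %in% no_ictal) && config$duration > 20) {
      ict <- with_seed(derive_seed(cfg_e$seed, 29L), {
        k <- sample(1:2, 1)
        d <- stats::runif(k, 8, 15)
        o <- stats::runif(k, 0, config$duration - d)
        data.frame(onset = o, duration = d)
      })
      rec <- inject_spike_wave(rec, ict, cfg_e, amplitude_scale = 1.5,
                               type = "ictal")
    }
    recs[[i]] <- rec
  }
  recs
}

#' Simulate single-channel benchmark-style records
#'
#' Emulates the public single-channel epilepsy benchmark format: 23.6 s
#' records sampled at 173.61 Hz, i.e. `floor(23.6 * 173.61) = 4097` samples
#' each. `kind = "healthy"` yields awake background activity with no event
#' annotations; `kind = "ictal"` yields continuous high-amplitude rhythmic
#' spike-and-wave discharge over the whole record.
#'
#' @param kind `"healthy"` or `"ictal"`.
#' @param n_segments number of records to generate.
#' @param seed integer seed.
#' @return List of single-channel [raw_recording()] objects.
#' @export
simulate_bonn_style <- function(kind = c("healthy", "ictal"), n_segments = 100,
                                seed = 1) {
  kind <- match.arg(kind)
  if (!is_count(n_segments)) stopf("`n_segments` must be a positive integer")
  base <- simulation_config(n_channels = 1, rate = 173.61, duration = 23.6,
                            background_bands = list(c(10, 25), c(19, 6)),
                            noise_scale = 15, event_amplitude = 400,
                            event_freq = 3, seed = seed)
  lapply(seq_len(n_segments), function(i) {
    cfg <- base
    cfg$seed <- derive_seed(seed, i + ifelse(kind == "ictal", 50000L, 0L))
    rec <- simulate_background(cfg, subject_id = sprintf("%s_%03d", kind, i))
    if (kind == "ictal")   # one discharge spanning the whole (floored) record
      rec <- inject_spike_wave(rec, list(c(0, rec_duration(rec))), cfg,
                               type = "ictal")
    rec
  })
}
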