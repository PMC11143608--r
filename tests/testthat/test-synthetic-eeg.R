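short_cfg <- function(...) {
  defaults <- list(n_channels = 2, rate = 250, duration = 10, seed = 5,
                   background_bands = list(c(10, 20)), noise_scale = 8)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

test_that("background simulation is deterministic and respects the zero case", {
  cfg <- short_cfg()
  a <- simulate_background(cfg)
  b <- simulate_background(cfg)
  expect_identical(a$signal, b$signal)
  expect_equal(a$group, "healthy")
  expect_equal(dim(a$signal), c(2L, floor(cfg$duration * cfg$rate)))

  cfg2 <- short_cfg(seed = 6)
  expect_false(identical(a$signal, simulate_background(cfg2)$signal))

  # all band amplitudes and the noise scale at zero: an all-zero signal
  zero_cfg <- simulation_config(n_channels = 2, rate = 250, duration = 10,
                                seed = 5, background_bands = list(c(10, 0)),
                                noise_scale = 0)
  zero <- simulate_background(zero_cfg)
  expect_true(all(zero$signal == 0))

  expect_error(simulation_config(duration = 0), "duration")
  expect_error(simulation_config(rate = -1), "rate")
})

test_that("a dominant 10 Hz band shows up as the periodogram peak", {
  cfg <- short_cfg(background_bands = list(c(10, 40)), noise_scale = 2,
                   duration = 20)
  rec <- simulate_background(cfg)
  for (ch in 1:2)
    expect_lt(abs(peak_frequency(rec$signal[ch, ], cfg$rate) - 10), 0.5)
})

test_that("spike-wave injection: no-op, peak count, band power, range check", {
  cfg <- short_cfg(n_channels = 1, rate = 500, duration = 12,
                   background_bands = list(c(10, 15)), noise_scale = 10,
                   event_amplitude = 150, event_freq = 3)
  rec <- simulate_background(cfg)

  # empty event list is the identity
  expect_identical(inject_spike_wave(rec, list(), cfg), rec)

  ev <- inject_spike_wave(rec, list(c(4, 2)), cfg)
  expect_equal(ev$group, "EP")
  # non-event samples unchanged
  pre <- 1:floor(4 * cfg$rate)
  expect_identical(ev$signal[, pre], rec$signal[, pre])

  # one 2 s event at 3 Hz carries exactly 6 spike peaks; the threshold
  # 3 * sd(background) sits between the slow-wave and spike amplitudes
  win <- (floor(4 * cfg$rate) + 1):floor(6 * cfg$rate)
  thr <- 3 * sd(rec$signal[1, ])
  added <- ev$signal[1, win] - rec$signal[1, win]   # the injected discharge trace
  expect_identical(count_peaks(added, thr), 6L)
  # the threshold separates spikes from slow waves: no peaks survive at
  # spike level + margin, all six do at wave level
  expect_identical(count_peaks(added, 1.4 * cfg$event_amplitude), 0L)

  # delta-band (2-4 Hz) power rises over the event window vs a matched
  # background window
  bp_ev <- band_power(ev$signal[1, win], cfg$rate, 2, 4)
  bp_bg <- band_power(ev$signal[1, pre[1:length(win)]], cfg$rate, 2, 4)
  expect_gt(bp_ev, 2 * bp_bg)

  expect_error(inject_spike_wave(rec, list(c(11, 5)), cfg), "outside")
})

test_that("cohort simulation: counts, labels, determinism, no-ictal fraction", {
  cfg <- short_cfg(n_channels = 3, duration = 30, rate = 200)
  recs <- simulate_cohort(21, 14, cfg)
  expect_length(recs, 35)
  groups <- vapply(recs, `[[`, character(1), "group")
  expect_identical(sum(groups == "healthy"), 21L)
  expect_identical(sum(groups == "EP"), 14L)
  ids <- vapply(recs, `[[`, character(1), "subject_id")
  expect_false(anyDuplicated(ids) > 0)

  # label soundness: EP iff at least one event injected
  for (r in recs) {
    has_events <- !is.null(r$events) && nrow(r$events) > 0
    expect_identical(r$group == "EP", has_events)
  }
  # a fraction of EP subjects has interictal events only
  ep <- recs[groups == "EP"]
  n_no_ictal <- sum(vapply(ep, function(r) !any(r$events$type == "ictal"),
                           logical(1)))
  expect_identical(n_no_ictal, 3L)

  recs2 <- simulate_cohort(21, 14, cfg)
  expect_identical(lapply(recs, `[[`, "signal"), lapply(recs2, `[[`, "signal"))
  cfg2 <- short_cfg(n_channels = 3, duration = 30, rate = 200, seed = 99)
  recs3 <- simulate_cohort(21, 14, cfg2)
  expect_false(identical(recs[[1]]$signal, recs3[[1]]$signal))

  one <- simulate_cohort(1, 0, cfg)
  expect_length(one, 1)
  expect_null(one[[1]]$events)
  expect_error(simulate_cohort(0, 0, cfg), "at least one")
})

test_that("benchmark-style records have 4097 samples at 173.61 Hz", {
  healthy <- simulate_bonn_style("healthy", n_segments = 3, seed = 2)
  expect_length(healthy, 3)
  for (r in healthy) {
    expect_identical(nrow(r$signal), 1L)
    expect_identical(ncol(r$signal), 4097L)  # floor(23.6 * 173.61)
    expect_equal(r$rate, 173.61)
    expect_null(r$events)
    expect_equal(r$group, "healthy")
  }
  ictal <- simulate_bonn_style("ictal", n_segments = 2, seed = 2)
  for (r in ictal) {
    expect_equal(r$group, "EP")
    # continuous rhythmic discharge: delta band dominates vs healthy record
    expect_gt(band_power(r$signal[1, ], r$rate, 2, 4),
              5 * band_power(healthy[[1]]$signal[1, ], r$rate, 2, 4))
  }
  expect_error(simulate_bonn_style("other", 1, 1), "arg")
})

test_that("separability knob: zero event amplitude removes the group difference", {
  cfg <- short_cfg(n_channels = 1, duration = 20, rate = 200,
                   event_amplitude = 0)
  recs <- simulate_cohort(8, 8, cfg)
  groups <- vapply(recs, `[[`, character(1), "group")
  bp <- vapply(recs, function(r) band_power(r$signal[1, ], r$rate, 2, 4),
               numeric(1))
  # with amplitude 0 the injected template is identically zero, so band
  # powers are exchangeable between groups
  p <- stats::wilcox.test(bp[groups == "EP"], bp[groups == "healthy"])$p.value
  expect_gt(p, 0.05)

  cfg_hi <- short_cfg(n_channels = 1, duration = 20, rate = 200,
                      event_amplitude = 200)
  recs_hi <- simulate_cohort(8, 8, cfg_hi)
  bp_hi <- vapply(recs_hi, function(r) band_power(r$signal[1, ], r$rate, 2, 4),
                  numeric(1))
  p_hi <- stats::wilcox.test(bp_hi[groups == "EP"], bp_hi[groups == "healthy"])$p.value
  expect_lt(p_hi, 0.05)
})
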