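# One-deflection trace: a single-cycle sine whose peak-to-trough excursion
# equals `amp`, placed at `at_s`, on an otherwise flat trace.
one_deflection <- function(amp, at_s = 5, dur_s = 10, fs = 200, width_s = 0.5) {
  x <- numeric(dur_s * fs)
  wl <- width_s * fs
  i <- round(at_s * fs) + seq_len(wl)
  x[i] <- amp / 2 * sin(2 * pi * seq_len(wl) / wl)
  eog_trace(x, fs, "LOC")
}

test_that("amplitude threshold is applied strictly to peak-to-trough excursions", {
  ev <- detect_eye_movements(one_deflection(30))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude_uv, 30, tolerance = 0.05)
  expect_equal(ev$time_s, 5.25, tolerance = 0.15)

  expect_equal(nrow(detect_eye_movements(one_deflection(20))), 0L)
  # exactly 25 uV is NOT an event (strict inequality); unfiltered path keeps
  # the excursion arithmetic exact
  expect_equal(nrow(detect_eye_movements(one_deflection(25), band_hz = NULL)), 0L)
  expect_equal(nrow(detect_eye_movements(one_deflection(25 + 1e-6), band_hz = NULL)), 1L)

  # flat trace: nothing to detect
  expect_equal(nrow(detect_eye_movements(eog_trace(numeric(2000), 200, "LOC"))), 0L)
  # sampling rate below twice the band edge is refused
  expect_error(detect_eye_movements(eog_trace(rnorm(100), 15, "LOC")),
               "sampling rate")
})

test_that("detector is threshold-monotone and scale-covariant", {
  set.seed(7)
  ev_tab <- data.frame(time_s = seq(2, 110, by = 4),
                       amplitude_uv = runif(28, 26, 80), channel = "LOC")
  tr <- simulate_eog(ev_tab, duration_s = 120, noise_sd = 2)$loc
  counts <- sapply(c(20, 25, 30, 40, 60), function(th) {
    nrow(detect_eye_movements(tr, threshold_uv = th))
  })
  expect_true(all(diff(counts) <= 0))

  scaled <- eog_trace(tr$samples * 1.5, tr$sampling_rate, "LOC")
  expect_gte(nrow(detect_eye_movements(scaled)), nrow(detect_eye_movements(tr)))
})

test_that("refractory interval collapses multi-lobed waveforms into one event", {
  fs <- 200
  x <- numeric(5 * fs)
  # triphasic wiggle: three >25 uV excursions within 0.15 s
  i <- fs + seq_len(0.15 * fs)
  x[i] <- 20 * sin(2 * pi * seq_along(i) / (0.1 * fs))
  tr <- eog_trace(x, fs, "LOC")
  expect_equal(nrow(detect_eye_movements(tr, band_hz = NULL, refractory_s = 0.2)), 1L)
  expect_gt(nrow(detect_eye_movements(tr, band_hz = NULL, refractory_s = 0.01)), 1L)
})

test_that("epoch binning places, deduplicates and bounds events correctly", {
  h <- hypnogram(rep("REM", 10))
  ev1 <- data.frame(time_s = 31, amplitude_uv = 40, channel = "LOC")
  c1 <- count_events_by_epoch(ev1, h)
  expect_equal(as.integer(c1), c(0L, 1L, rep(0L, 8)))

  expect_equal(sum(count_events_by_epoch(data.frame(time_s = numeric(0),
                                                    amplitude_uv = numeric(0),
                                                    channel = character(0)), h)), 0L)

  # binocular pair within 0.2 s counts once; same-channel pair does not merge
  ev2 <- data.frame(time_s = c(10, 10.1), amplitude_uv = c(40, 38),
                    channel = c("LOC", "ROC"))
  expect_equal(sum(count_events_by_epoch(ev2, h)), 1L)
  ev3 <- data.frame(time_s = c(10, 10.1), amplitude_uv = c(40, 38),
                    channel = c("LOC", "LOC"))
  expect_equal(sum(count_events_by_epoch(ev3, h)), 2L)

  # out-of-span events are rejected, not dropped silently
  expect_error(count_events_by_epoch(data.frame(time_s = 301, amplitude_uv = 40,
                                                channel = "LOC"), h),
               "outside the recording span")

  # random events: binned total equals deduplicated count, never more than raw
  set.seed(11)
  ev <- data.frame(time_s = runif(100, 0, 300), amplitude_uv = 40,
                   channel = sample(c("LOC", "ROC"), 100, replace = TRUE))
  cc <- count_events_by_epoch(ev, h)
  expect_equal(sum(cc) + attr(cc, "n_merged"), 100L)
  expect_lte(sum(cc), 100L)
  # and with merging disabled, brute-force binning agrees
  cc0 <- count_events_by_epoch(ev, h, dedup_window_s = 0)
  brute <- tabulate(floor(ev$time_s / 30) + 1, nbins = 10)
  expect_equal(as.integer(cc0), brute)
})
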