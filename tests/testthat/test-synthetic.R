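test_that("simulated hypnograms have the designed night structure", {
  spec <- cohort_spec()
  set.seed(71)
  for (rep in 1:10) {
    h <- simulate_hypnogram(spec, sample(c("TRD", "HV"), 1),
                            sample(c("baseline", "post_treatment"), 1))
    expect_length(h$stages, spec$in_bed_min * 2)
    p <- segment_rem_periods(h)
    expect_gte(nrow(p), 2)                      # several distinct REM periods
    expect_true(all(p$rem_minutes >= 3))
    expect_false(is.na(sleep_onset(h)))
  }
  # generator self-consistency: segmented REM latency recovers the model mean
  set.seed(72)
  rls <- replicate(120, rem_latency(simulate_hypnogram(spec, "HV", "baseline")))
  se <- sd(rls) / sqrt(length(rls))
  expect_lt(abs(mean(rls) - spec$latency_mean[["HV"]]), 3 * se + 1)
})

test_that("event trains are Poisson at the designed rates with compensation", {
  spec <- cohort_spec()
  set.seed(73)
  h <- simulate_hypnogram(spec, "TRD", "baseline")
  # zero rate: no events
  expect_equal(nrow(simulate_em_events(h, 0, 1.35, spec)), 0L)

  # rate recovery on one night repeated: first-period rate = base x mult
  base <- 1.2; mult <- 1.4
  reps <- 300
  r1 <- tn <- numeric(reps)
  p <- segment_rem_periods(h)
  for (i in seq_len(reps)) {
    ev <- simulate_em_events(h, base, mult, spec)
    counts <- count_events_by_epoch(ev, h, dedup_window_s = 0)
    r1[i] <- rd1(counts, p, h)
    tn[i] <- total_night_rd(counts, h)
  }
  expect_lt(abs(mean(r1) - base * mult), 3 * sd(r1) / sqrt(reps))
  expect_lt(abs(mean(tn) - base), 3 * sd(tn) / sqrt(reps))
  # all event amplitudes exceed the 25 uV criterion
  ev <- simulate_em_events(h, 2, 1, spec)
  expect_true(all(ev$amplitude_uv > 25))
  expect_true(all(ev$time_s >= 0 & ev$time_s < 30 * length(h$stages)))
})

test_that("synthetic EOG traces carry implanted deflections and honest ground truth", {
  set.seed(74)
  # no events, no noise: flat
  flat <- simulate_eog(data.frame(time_s = numeric(0), amplitude_uv = numeric(0)),
                       duration_s = 30, noise_sd = 0)
  expect_true(all(flat$loc$samples == 0))
  # sub-threshold amplitudes are not detectable
  ev_small <- data.frame(time_s = seq(2, 28, 2), amplitude_uv = 10)
  tr <- simulate_eog(ev_small, 30, noise_sd = 1)
  expect_lte(nrow(detect_eye_movements(tr$loc)), 1)
  # channels are anti-phase copies of the same saccades
  ev <- data.frame(time_s = 5, amplitude_uv = 60)
  tr2 <- simulate_eog(ev, 10, noise_sd = 0)
  expect_equal(tr2$loc$samples, -tr2$roc$samples)
  expect_error(simulate_eog(data.frame(time_s = 9.9, amplitude_uv = 40), 10),
               "within the trace span")
})

test_that("clinical simulation respects the floor, the link, and the response rule", {
  spec <- cohort_spec()
  set.seed(75)
  rd1v <- rlnorm(63, log(1.5), 0.5)
  cl <- simulate_clinical(spec, rd1v)
  expect_true(all(cl$hamd_baseline >= spec$hamd_floor))
  expect_equal(sum(is.na(cl$responder)), spec$n_missing_response)
  ok <- !is.na(cl$responder)
  # labels are consistent with the inclusive 50% rule applied to the scores
  expect_equal(label_responders(cl$hamd_baseline[ok], cl$hamd_day1[ok]),
               cl$responder[ok])
  # responder count is calibrated: across cohorts the mean is ~ n_responders
  counts <- replicate(60, sum(simulate_clinical(spec, rd1v)$responder, na.rm = TRUE))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - spec$n_responders), 3 * se + 0.5)
  # zero slope: response independent of RD1 (prediction null)
  spec0 <- cohort_spec(response_link_slope = 0)
  cl0 <- simulate_clinical(spec0, rd1v)
  expect_equal(sum(is.na(cl0$responder)), spec0$n_missing_response)
})

test_that("cohort simulation is reproducible and carries the designed effects", {
  spec <- cohort_spec(n_trd = 14, n_hv = 10, n_responders = 4,
                      n_missing_response = 1)
  a <- simulate_cohort(spec, seed = 123)
  b <- simulate_cohort(spec, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 14 * 2 + 10)
  expect_true(all(c("rd1", "rl_minutes", "hamd_baseline", "responder") %in% names(a)))
  # clinical columns constant within subject, absent for HV
  expect_true(all(is.na(a$responder[a$group == "HV"])))
  trd_base <- a$group == "TRD" & a$night == "baseline"
  trd_post <- a$group == "TRD" & a$night == "post_treatment"
  # treatment lowers RD1 on average in this designed cohort
  expect_lt(mean(a$rd1[trd_post], na.rm = TRUE),
            mean(a$rd1[trd_base], na.rm = TRUE))
})
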