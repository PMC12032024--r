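test_that("REM periods merge, split, and discard per the 15-min / 3-min rules", {
  expect_equal(nrow(segment_rem_periods(hypnogram(rep("S2", 40)))), 0L)

  # 5-min gap merges two REM runs into one period
  h <- hypnogram(c(rep("S2", 20), rep("REM", 6), rep("S2", 10), rep("REM", 8),
                   rep("S2", 40)))
  p <- segment_rem_periods(h)
  expect_equal(nrow(p), 1L)
  expect_equal(p$start, 21L)
  expect_equal(p$end, 45L)
  expect_equal(p$rem_minutes, 7.0)
  expect_true(p$completed)

  # exactly 15 min of NREM separates
  h2 <- hypnogram(c(rep("REM", 6), rep("S2", 30), rep("REM", 6)))
  expect_equal(nrow(segment_rem_periods(h2)), 2L)
  # 14.5 min does not
  h3 <- hypnogram(c(rep("REM", 6), rep("S2", 29), rep("REM", 6)))
  expect_equal(nrow(segment_rem_periods(h3)), 1L)

  # an isolated 2-min REM run is discarded
  h4 <- hypnogram(c(rep("S2", 10), rep("REM", 4), rep("S2", 40)))
  expect_equal(nrow(segment_rem_periods(h4)), 0L)

  # period truncated by end of night is not completed
  h5 <- hypnogram(c(rep("S2", 40), rep("REM", 8)))
  p5 <- segment_rem_periods(h5)
  expect_false(p5$completed)
})

test_that("segmentation equals the brute-force oracle and is idempotent", {
  # exhaustive over {S2, REM} strings up to length 12
  for (len in 1:12) {
    grids <- expand.grid(rep(list(c("S2", "REM")), len), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grids))) {
      st <- as.character(grids[r, ])
      got <- segment_rem_periods(hypnogram(st))
      want <- oracle_segment(st)
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    }
  }
  # random soup including wake/unscored, both gap conventions
  set.seed(21)
  for (rep in 1:30) {
    st <- random_stages(300)
    h <- hypnogram(st)
    for (gw in c(TRUE, FALSE)) {
      got <- segment_rem_periods(h, gap_counts_wake = gw)
      want <- oracle_segment(st, gap_counts_wake = gw)
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    }
    # idempotence: re-segmenting the union of returned periods returns them
    got <- segment_rem_periods(h)
    if (nrow(got)) {
      keep <- unlist(lapply(seq_len(nrow(got)), function(i) got$start[i]:(got$end[i] - 1L)))
      st2 <- st
      st2[setdiff(which(st == "REM"), keep)] <- "S2"
      again <- segment_rem_periods(hypnogram(st2))
      expect_equal(as.data.frame(again)[c("start", "end", "rem_minutes", "span_minutes")],
                   as.data.frame(got)[c("start", "end", "rem_minutes", "span_minutes")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("REM latency, time, percent and efficiency follow their definitions", {
  # onset epoch 5 (1-based), first REM period at epoch 145: 70 min elapsed
  st <- c(rep("W", 4), rep("S2", 140), rep("REM", 10), rep("S2", 40))
  h <- hypnogram(st)
  expect_equal(rem_latency(h), 70.0)
  expect_equal(rem_time(h), 5.0)
  expect_true(is.na(rem_latency(hypnogram(rep("S2", 20)))))
  # REM at the onset epoch boundary: latency 0 needs REM starting right at onset
  h0 <- hypnogram(c("S2", rep("REM", 7), rep("S2", 40)))
  expect_equal(rem_latency(h0), 0.5)

  expect_equal(rem_percent(hypnogram(c(rep("S2", 270), rep("REM", 90)))), 25.0)
  expect_equal(rem_percent(hypnogram(c(rep("S2", 100)))), 0.0)

  # one completed period: 16 of 17 min in REM -> 94.1%
  st6 <- c(rep("S2", 10), rep("REM", 16), rep("S2", 2), rep("REM", 16),
           rep("S2", 40))
  p6 <- segment_rem_periods(hypnogram(st6))
  expect_equal(rem_efficiency(p6), 100 * 16 / 17, tolerance = 1e-12)
  # uninterrupted periods: 100%
  p7 <- segment_rem_periods(hypnogram(c(rep("S2", 10), rep("REM", 10), rep("S2", 40))))
  expect_equal(rem_efficiency(p7), 100.0)
})

test_that("densities are correct ratios and invariant to count permutations", {
  st <- c(rep("S2", 20), rep("REM", 28), rep("S2", 40), rep("REM", 20),
          rep("S2", 40))
  h <- hypnogram(st)
  p <- segment_rem_periods(h)
  counts <- integer(length(st))
  counts[21:48] <- 3L   # 84 movements in the 14-min first period
  expect_equal(rd1(counts, p, h), 84 / 14)
  expect_equal(total_night_rd(counts, h), 84 / 24)

  # movement-free night
  expect_equal(rd1(integer(length(st)), p, h), 0)
  # permuting counts among REM epochs leaves total-night density unchanged
  set.seed(31)
  counts2 <- integer(length(st))
  rem_idx <- which(st == "REM")
  counts2[rem_idx] <- rpois(length(rem_idx), 2)
  perm <- counts2
  perm[rem_idx] <- sample(counts2[rem_idx])
  expect_equal(total_night_rd(perm, h), total_night_rd(counts2, h))
  # events in non-REM epochs are excluded from the numerator
  counts3 <- counts2
  counts3[which(st == "S2")] <- 5L
  expect_equal(total_night_rd(counts3, h), total_night_rd(counts2, h))
})

test_that("night_metrics assembles the panel and marks undefined metrics NA", {
  set.seed(41)
  spec <- cohort_spec()
  for (rep in 1:10) {
    hyp <- simulate_hypnogram(spec, "TRD", "baseline")
    ev <- simulate_em_events(hyp, 1.3, 1.3, spec)
    counts <- count_events_by_epoch(ev, hyp, dedup_window_s = 0)
    nm <- night_metrics(hyp, counts)
    o <- oracle_metrics(hyp$stages, counts)
    for (f in names(o)) expect_equal(nm[[f]], o[[f]], tolerance = 1e-12)
    # periods sum rule: REM minutes inside periods never exceed REM time
    p <- attr(nm, "rem_periods")
    expect_lte(sum(p$rem_minutes), nm$rem_time)
  }
  # REM-free night: REM metrics NA, architecture present
  nm0 <- night_metrics(hypnogram(c(rep("S2", 100), rep("W", 10))), integer(110))
  expect_true(is.na(nm0$rd1) && is.na(nm0$rl_minutes) && is.na(nm0$total_night_rd))
  expect_false(is.na(nm0$tst))
})
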