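#' Segment a hypnogram into REM periods
#'
#' REM epochs separated by less than `gap_min` minutes of intervening
#' non-REM are grouped into one candidate period; a gap of `gap_min` minutes
#' or more starts a new period. Candidates whose cumulative REM time falls
#' below `min_rem_min` minutes are discarded. A surviving period is
#' `completed` when it is followed by at least `gap_min` minutes of non-REM
#' before the night's final waking; a period truncated by the end of the
#' night is not completed.
#'
#' By default wake and unscored epochs count toward the separating gap
#' alongside non-REM sleep (`gap_counts_wake = TRUE`); with `FALSE` only
#' non-REM *sleep* epochs (S1--S4) count.
#'
#' @param hyp A [hypnogram()].
#' @param min_rem_min Minimum cumulative REM minutes for a period to survive.
#'   Default 3.
#' @param gap_min Minutes of non-REM required to separate two periods (and to
#'   terminate a completed period). Default 15.
#' @param gap_counts_wake Should wake/unscored epochs count toward gaps?
#'   Default `TRUE`.
#' @return A data frame of class `"rem_periods"`, one row per surviving
#'   period in temporal order: `start` (first REM epoch, 1-based), `end` (one
#'   past the last REM epoch), `rem_minutes`, `span_minutes`, `completed`.
#'   Zero rows when no candidate survives.
#' @export
segment_rem_periods <- function(hyp, min_rem_min = 3, gap_min = 15,
                                gap_counts_wake = TRUE) {
  stopifnot(inherits(hyp, "hypnogram"))
  stages <- hyp$stages
  rem <- which(stages == "REM")
  empty <- structure(
    data.frame(start = integer(0), end = integer(0),
               rem_minutes = numeric(0), span_minutes = numeric(0),
               completed = logical(0)),
    class = c("rem_periods", "data.frame"))
  if (!length(rem)) return(empty)
  gap_epochs <- round(gap_min * 2)

  counts_toward_gap <- if (gap_counts_wake) {
    stages != "REM"
  } else {
    stages %in% c("S1", "S2", "S3", "S4")
  }
  csum <- cumsum(counts_toward_gap)
  # gap between consecutive REM epochs = qualifying epochs strictly between
  gaps <- if (length(rem) > 1) csum[rem[-1] - 1L] - csum[rem[-length(rem)]] else numeric(0)
  grp <- cumsum(c(1L, as.integer(gaps >= gap_epochs)))
  grp <- factor(grp, levels = unique(grp))  # keep temporal order past 9 groups

  starts <- tapply(rem, grp, min)
  ends <- tapply(rem, grp, max) + 1L
  nrem <- tapply(rem, grp, length)
  out <- data.frame(start = as.integer(starts), end = as.integer(ends),
                    rem_minutes = 0.5 * as.numeric(nrem),
                    span_minutes = 0.5 * (as.numeric(ends) - as.numeric(starts)))
  out <- out[out$rem_minutes >= min_rem_min, , drop = FALSE]
  if (!nrow(out)) return(empty)

  fw <- final_waking(hyp)
  out$completed <- vapply(seq_len(nrow(out)), function(i) {
    e <- out$end[i]
    nxt_rem <- rem[rem >= e]
    stretch_end <- if (length(nxt_rem)) min(nxt_rem[1L], fw) else fw
    if (stretch_end <= e) return(FALSE)
    span <- seq.int(e, stretch_end - 1L)
    sum(counts_toward_gap[span]) >= gap_epochs
  }, logical(1))
  rownames(out) <- NULL
  class(out) <- c("rem_periods", "data.frame")
  out
}

#' REM latency (minutes)
#'
#' Elapsed time from sleep onset to the start of the first REM period,
#' including any intervening wake.
#'
#' @param hyp A [hypnogram()].
#' @param periods Optional precomputed [segment_rem_periods()] result.
#' @return Minutes, or `NA_real_` when there is no sleep onset or no REM
#'   period.
#' @export
rem_latency <- function(hyp, periods = segment_rem_periods(hyp)) {
  on <- sleep_onset(hyp)
  if (is.na(on) || !nrow(periods)) return(NA_real_)
  0.5 * (periods$start[1L] - on)
}

#' REM time (minutes)
#'
#' Total minutes of REM sleep between sleep onset and final waking -- all REM
#' epochs, whether or not they fall inside a surviving REM period.
#'
#' @param hyp A [hypnogram()].
#' @return Minutes, or `NA_real_` when there is no sleep onset.
#' @export
rem_time <- function(hyp) {
  w <- .analysis_window(hyp)
  if (!length(w)) return(NA_real_)
  0.5 * sum(hyp$stages[w] == "REM")
}

#' REM percent
#'
#' Time in REM sleep as a percentage of total sleep time.
#'
#' @param hyp A [hypnogram()].
#' @return Percent, or `NA_real_` when total sleep time is zero or undefined.
#' @export
rem_percent <- function(hyp) {
  tst <- total_sleep_time(hyp)
  if (is.na(tst) || tst <= 0) return(NA_real_)
  100 * rem_time(hyp) / tst
}

#' REM efficiency
#'
#' 100 x REM minutes within completed REM periods divided by the total span
#' of those completed periods: the fraction of completed-period span actually
#' spent in REM.
#'
#' @param periods A [segment_rem_periods()] result.
#' @return Percent, or `NA_real_` when the night has no completed period.
#' @export
rem_efficiency <- function(periods) {
  cp <- periods[periods$completed, , drop = FALSE]
  if (!nrow(cp)) return(NA_real_)
  100 * sum(cp$rem_minutes) / sum(cp$span_minutes)
}

#' Total-night REM density (eye movements per minute of REM)
#'
#' Eye movements falling in REM epochs between sleep onset and final waking,
#' divided by the night's total REM time. Movements scored during non-REM
#' epochs are excluded from the numerator, matching the REM-time denominator.
#'
#' @param epoch_counts Per-epoch eye-movement counts from
#'   [count_events_by_epoch()].
#' @param hyp The night's [hypnogram()].
#' @return Counts/min, or `NA_real_` when REM time is zero or undefined.
#' @export
total_night_rd <- function(epoch_counts, hyp) {
  rt <- rem_time(hyp)
  if (is.na(rt) || rt <= 0) return(NA_real_)
  w <- .analysis_window(hyp)
  w_rem <- w[hyp$stages[w] == "REM"]
  sum(epoch_counts[w_rem]) / rt
}

#' First-REM-period density, RD1 (eye movements per minute of REM)
#'
#' Eye movements within the REM epochs of the first REM period divided by
#' that period's REM minutes.
#'
#' @param epoch_counts Per-epoch eye-movement counts.
#' @param periods A [segment_rem_periods()] result for the same night.
#' @param hyp The night's [hypnogram()] (identifies which epochs in the
#'   first period are REM).
#' @return Counts/min, or `NA_real_` when the night has no REM period.
#' @export
rd1 <- function(epoch_counts, periods, hyp) {
  if (!nrow(periods)) return(NA_real_)
  span <- seq.int(periods$start[1L], periods$end[1L] - 1L)
  span_rem <- span[hyp$stages[span] == "REM"]
  sum(epoch_counts[span_rem]) / periods$rem_minutes[1L]
}

#' Compute the full per-night metric panel
#'
#' Assembles REM latency, RD1, total-night REM density, total sleep time,
#' REM time, REM percent, REM efficiency, slow-wave sleep, wake after sleep
#' onset and sleep efficiency for one night. Metrics that are undefined for
#' the night (e.g. REM-dependent metrics on a REM-free night) are reported
#' as `NA`, never as silent zeros.
#'
#' @param hyp A [hypnogram()].
#' @param epoch_counts Per-epoch eye-movement counts, or `NULL` when no eye
#'   movement data are available (density metrics are then `NA`).
#' @return A one-row data frame with columns `subject_id`, `night`,
#'   `rl_minutes`, `rd1`, `total_night_rd`, `tst`, `rem_time`, `rem_percent`,
#'   `rem_efficiency`, `sws`, `waso`, `se`. The segmented REM-period table is
#'   attached as attribute `"rem_periods"`.
#' @export
night_metrics <- function(hyp, epoch_counts = NULL) {
  periods <- segment_rem_periods(hyp)
  out <- data.frame(
    subject_id = hyp$subject_id,
    night = hyp$night,
    rl_minutes = rem_latency(hyp, periods),
    rd1 = if (is.null(epoch_counts)) NA_real_ else rd1(epoch_counts, periods, hyp),
    total_night_rd = if (is.null(epoch_counts)) NA_real_ else total_night_rd(epoch_counts, hyp),
    tst = total_sleep_time(hyp),
    rem_time = rem_time(hyp),
    rem_percent = rem_percent(hyp),
    rem_efficiency = rem_efficiency(periods),
    sws = sws_minutes(hyp),
    waso = waso_minutes(hyp),
    se = sleep_efficiency(hyp),
    stringsAsFactors = FALSE
  )
  attr(out, "rem_periods") <- periods
  out
}
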