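#' Construct an electrooculogram trace
#'
#' A single EOG channel as a regularly sampled voltage series in microvolts,
#' aligned so that sample 1 falls at `start_s` seconds after hypnogram epoch 1
#' begins (i.e. after lights out).
#'
#' @param samples Numeric vector of voltages in microvolts.
#' @param sampling_rate Sampling rate in Hz (nominally 200).
#' @param channel `"LOC"` or `"ROC"` (left / right outer canthus).
#' @param start_s Offset of the first sample from epoch 1, in seconds.
#' @return An object of class `"eog_trace"`.
#' @export
eog_trace <- function(samples, sampling_rate = 200, channel = c("LOC", "ROC"),
                      start_s = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (!length(samples)) stop("EOG trace must contain samples")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel = channel, start_s = start_s),
            class = "eog_trace")
}

#' @export
print.eog_trace <- function(x, ...) {
  cat(sprintf("<eog_trace> %s: %d samples @ %g Hz (%.1f s)\n", x$channel,
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Detect rapid eye movements by amplitude threshold
#'
#' A rapid eye movement is scored wherever the peak-to-trough voltage
#' excursion of the (optionally band-limited) EOG signal between consecutive
#' local extrema strictly exceeds `threshold_uv`. No duration criterion is
#' applied: a deflection of any width qualifies provided its excursion clears
#' the threshold. Band-limiting (default 0.3--10 Hz, zero-phase Butterworth)
#' suppresses slow drift and high-frequency noise before extrema are located
#' at the zero crossings of the first difference. A per-channel refractory
#' interval collapses multi-lobed saccade waveforms into one event.
#'
#' @param trace An [eog_trace()].
#' @param threshold_uv Detection threshold in microvolts; events require a
#'   strictly greater excursion. Default 25.
#' @param refractory_s Minimum separation between events on one channel, in
#'   seconds. Default 0.1.
#' @param band_hz Length-2 numeric pass band in Hz, or `NULL` to skip
#'   filtering. Default `c(0.3, 10)`.
#' @return A data frame with one row per event: `time_s` (seconds from epoch
#'   1), `amplitude_uv` (peak-to-trough excursion), `channel`.
#' @export
detect_eye_movements <- function(trace, threshold_uv = 25, refractory_s = 0.1,
                                 band_hz = c(0.3, 10)) {
  stopifnot(inherits(trace, "eog_trace"), threshold_uv > 0)
  fs <- trace$sampling_rate
  x <- trace$samples
  if (!is.null(band_hz)) {
    band_hz <- sort(as.numeric(band_hz))
    if (fs < 2 * band_hz[2]) {
      stop("sampling rate ", fs, " Hz is below twice the band upper edge (",
           band_hz[2], " Hz)")
    }
    if (length(x) > 12) {  # filtfilt needs more samples than 3x filter order
      bf <- signal::butter(2, band_hz / (fs / 2), type = "pass")
      x <- signal::filtfilt(bf, x)
    }
  }
  ext <- .local_extrema(x)
  if (length(ext) < 2) {
    return(.empty_events())
  }
  exc <- abs(diff(x[ext]))
  hit <- which(exc > threshold_uv)
  if (!length(hit)) return(.empty_events())
  # event time: midpoint of the extrema pair bounding the excursion
  idx_mid <- (ext[hit] + ext[hit + 1L]) / 2
  times <- trace$start_s + (idx_mid - 1) / fs
  amps <- exc[hit]
  keep <- .apply_refractory(times, refractory_s)
  data.frame(time_s = times[keep], amplitude_uv = amps[keep],
             channel = trace$channel, stringsAsFactors = FALSE)
}

.empty_events <- function() {
  data.frame(time_s = numeric(0), amplitude_uv = numeric(0),
             channel = character(0), stringsAsFactors = FALSE)
}

# Indices of local extrema (sign changes of the first difference), including
# the endpoints of every monotone run. Flat segments contribute no extrema.
.local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  s <- s[s != 0]
  if (!length(s)) return(integer(0))
  dnz <- which(diff(x) != 0)
  # run-length encode the sign sequence of nonzero differences
  sgn <- sign(diff(x))[dnz]
  turn <- which(diff(sgn) != 0)
  ends <- dnz[c(turn, length(dnz))] + 1L   # end of each monotone run
  starts <- dnz[c(1L, turn + 1L)]          # start of each monotone run
  sort(unique(c(starts[1L], ends)))
}

# Greedy first-come refractory: keep an event only if it falls at least
# refractory_s after the previously kept one. Deterministic.
.apply_refractory <- function(times, refractory_s) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  keep
}

#' Bin eye-movement events into hypnogram epochs
#'
#' Events from both channels are merged with binocular double-count
#' suppression: a saccade registers on LOC and ROC, so events on different
#' channels closer than `dedup_window_s` are counted once. The deduplicated
#' events are then binned onto the 30-s epoch grid.
#'
#' @param events Data frame with `time_s` and `channel` columns, as produced
#'   by [detect_eye_movements()] (rows from both channels may be concatenated)
#'   or read from a pre-detected event table.
#' @param hyp The night's [hypnogram()].
#' @param dedup_window_s Coincidence window for binocular merging, seconds.
#'   Default 0.2. Set to 0 to disable merging.
#' @return Integer vector of per-epoch counts, length `length(hyp$stages)`.
#'   Attribute `n_merged` records how many events were suppressed. Events
#'   outside the recording span raise an error identifying them.
#' @export
count_events_by_epoch <- function(events, hyp, dedup_window_s = 0.2) {
  stopifnot(inherits(hyp, "hypnogram"))
  n_epochs <- length(hyp$stages)
  counts <- integer(n_epochs)
  if (!nrow(events)) {
    attr(counts, "n_merged") <- 0L
    return(counts)
  }
  span_s <- 30 * n_epochs
  bad <- which(events$time_s < 0 | events$time_s >= span_s)
  if (length(bad)) {
    stop("event(s) outside the recording span [0, ", span_s, ") s at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  ord <- order(events$time_s)
  t_s <- events$time_s[ord]
  ch <- as.character(events$channel[ord])
  keep <- logical(length(t_s))
  last_t <- -Inf
  last_ch <- ""
  for (i in seq_along(t_s)) {
    if (dedup_window_s > 0 && ch[i] != last_ch &&
        (t_s[i] - last_t) < dedup_window_s) {
      # binocular duplicate of the previously counted movement
      last_t <- t_s[i]
      last_ch <- ch[i]
      next
    }
    keep[i] <- TRUE
    last_t <- t_s[i]
    last_ch <- ch[i]
  }
  epoch <- floor(t_s[keep] / 30) + 1L
  tab <- tabulate(epoch, nbins = n_epochs)
  counts <- as.integer(tab)
  attr(counts, "n_merged") <- sum(!keep)
  counts
}
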