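#' @importFrom stats rbinom rgamma rlnorm rnorm rpois runif quantile sd median
#'   shapiro.test wilcox.test p.adjust plogis qnorm uniroot var complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

STAGE_LEVELS <- c("W", "S1", "S2", "S3", "S4", "REM", "UNSCORED")
SLEEP_STAGES <- c("S1", "S2", "S3", "S4", "REM")

#' Default mapping from stage tokens found in annotation files to the internal
#' R&K vocabulary
#'
#' Modern AASM-scored exports use N1/N2/N3 and "R"; the internal vocabulary is
#' the classical W, S1--S4, REM plus UNSCORED. N3 maps to S3 (S4 is then
#' unused), consistent with treating slow-wave sleep as stages 3+4 combined.
#'
#' @return Named character vector: names are accepted input tokens, values are
#'   internal stage labels.
#' @export
default_stage_map <- function() {
  c(
    W = "W", WAKE = "W", `0` = "W",
    S1 = "S1", N1 = "S1", `1` = "S1",
    S2 = "S2", N2 = "S2", `2` = "S2",
    S3 = "S3", N3 = "S3", `3` = "S3",
    S4 = "S4", `4` = "S4",
    REM = "REM", R = "REM", `5` = "REM",
    UNSCORED = "UNSCORED", U = "UNSCORED", `?` = "UNSCORED", A = "UNSCORED"
  )
}

#' Construct a scored-night hypnogram
#'
#' A hypnogram is the per-epoch sequence of visually scored sleep stages for
#' one recording night, on a fixed 30-second epoch grid, anchored to the
#' lights-out clock time. Epoch `i` (1-based) covers the half-open interval
#' `[(i-1)*30, i*30)` seconds from lights out.
#'
#' @param stages Character vector of stage labels, each one of
#'   `W, S1, S2, S3, S4, REM, UNSCORED`.
#' @param subject_id Opaque subject identifier.
#' @param night One of `"adaptation"`, `"baseline"`, `"post_treatment"`.
#' @param lights_out Clock time `"HH:MM:SS"` at which epoch 1 starts.
#' @param lights_on Clock time at which the recording ends; defaults to
#'   `lights_out` plus `30 * length(stages)` seconds. Must agree with the
#'   epoch count to within one epoch.
#' @param epoch_seconds Epoch duration; fixed at 30 s.
#' @return An object of class `"hypnogram"`.
#' @export
hypnogram <- function(stages, subject_id = "subject", night = "baseline",
                      lights_out = "23:00:00", lights_on = NULL,
                      epoch_seconds = 30) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  if (!identical(as.numeric(epoch_seconds), 30)) {
    stop("epoch_seconds must be 30")
  }
  night <- match.arg(night, c("adaptation", "baseline", "post_treatment"))
  span_s <- 30 * length(stages)
  if (is.null(lights_on)) {
    lights_on <- .sec_to_clock(.clock_to_sec(lights_out) + span_s)
  } else {
    clock_span <- (.clock_to_sec(lights_on) - .clock_to_sec(lights_out)) %% 86400
    if (abs(clock_span - span_s) > 30) {
      stop("lights_out -> lights_on span (", clock_span,
           " s) disagrees with epoch count (", span_s, " s) by more than one epoch")
    }
  }
  structure(
    list(subject_id = subject_id, night = night, epoch_seconds = 30,
         stages = stages, lights_out = lights_out, lights_on = lights_on),
    class = "hypnogram"
  )
}

.clock_to_sec <- function(x) {
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) != 3 || anyNA(p)) stop("clock time must be HH:MM:SS, got: ", x)
  p[1] * 3600 + p[2] * 60 + p[3]
}

.sec_to_clock <- function(s) {
  s <- round(s) %% 86400
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$stages)
  tab <- table(factor(x$stages, levels = STAGE_LEVELS))
  cat(sprintf("<hypnogram> %s / %s: %d epochs (%.1f min), lights %s-%s\n",
              x$subject_id, x$night, n, n * 0.5, x$lights_out, x$lights_on))
  cat("  ", paste(sprintf("%s:%d", names(tab)[tab > 0], tab[tab > 0]),
                  collapse = " "), "\n")
  invisible(x)
}

#' Sleep onset epoch
#'
#' Sleep onset is the first epoch of stage 2 sleep.
#'
#' @param hyp A [hypnogram()].
#' @return 1-based epoch index of the first S2 epoch, or `NA_integer_` when
#'   the night contains no stage-2 sleep.
#' @export
sleep_onset <- function(hyp) {
  i <- which(hyp$stages == "S2")
  if (length(i)) i[1L] else NA_integer_
}

#' Final waking epoch boundary
#'
#' One past the last epoch of any sleep stage; terminal wake (and terminal
#' unscored time) is excluded from all architecture metrics. `NA` when the
#' night contains no sleep at all.
#'
#' @param hyp A [hypnogram()].
#' @return 1-based exclusive end index, or `NA_integer_`.
#' @export
final_waking <- function(hyp) {
  i <- which(hyp$stages %in% SLEEP_STAGES)
  if (length(i)) i[length(i)] + 1L else NA_integer_
}

# Epochs of the analysis window [sleep_onset, final_waking); integer(0) when
# there is no sleep onset.
.analysis_window <- function(hyp) {
  on <- sleep_onset(hyp)
  if (is.na(on)) return(integer(0))
  fw <- final_waking(hyp)
  seq.int(on, fw - 1L)
}

#' Total sleep time (minutes)
#'
#' Minutes of sleep (stages 1--4 and REM) between sleep onset and final
#' morning wake-up. Unscored epochs count as neither sleep nor wake.
#'
#' @param hyp A [hypnogram()].
#' @return Minutes, or `NA_real_` when there is no sleep onset.
#' @export
total_sleep_time <- function(hyp) {
  w <- .analysis_window(hyp)
  if (!length(w)) return(NA_real_)
  0.5 * sum(hyp$stages[w] %in% SLEEP_STAGES)
}

#' Slow-wave sleep (minutes)
#'
#' Minutes of stages 3 and 4 between sleep onset and final waking.
#'
#' @inheritParams total_sleep_time
#' @return Minutes, or `NA_real_` when there is no sleep onset.
#' @export
sws_minutes <- function(hyp) {
  w <- .analysis_window(hyp)
  if (!length(w)) return(NA_real_)
  0.5 * sum(hyp$stages[w] %in% c("S3", "S4"))
}

#' Wake after sleep onset (minutes)
#'
#' Minutes awake between sleep onset and final waking; terminal wake after
#' the last sleep epoch is excluded.
#'
#' @inheritParams total_sleep_time
#' @return Minutes, or `NA_real_` when there is no sleep onset.
#' @export
waso_minutes <- function(hyp) {
  w <- .analysis_window(hyp)
  if (!length(w)) return(NA_real_)
  0.5 * sum(hyp$stages[w] == "W")
}

#' Sleep efficiency (percent)
#'
#' 100 x total minutes of sleep anywhere in the record divided by the in-bed
#' span from lights out to lights on.
#'
#' @inheritParams total_sleep_time
#' @return Percent in `[0, 100]`, or `NA_real_` for a zero-length span.
#' @export
sleep_efficiency <- function(hyp) {
  in_bed_min <- 0.5 * length(hyp$stages)
  if (in_bed_min <= 0) return(NA_real_)
  100 * (0.5 * sum(hyp$stages %in% SLEEP_STAGES)) / in_bed_min
}
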