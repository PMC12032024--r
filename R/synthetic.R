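#' Specification of a synthetic sleep-study cohort
#'
#' Collects every generator parameter in one place so a cohort can be
#' regenerated exactly. Defaults emulate a two-group study: a
#' treatment-resistant depression (TRD) group recorded at baseline and after
#' treatment, and healthy volunteers (HV) recorded at baseline. The designed
#' group structure is: shorter REM latency and elevated first-REM-period
#' density (RD1) in TRD at baseline with *no* group difference in
#' total-night REM density (the TRD elevation is a redistribution of eye
#' movements toward the first REM period with late-night compensation), a
#' treatment effect that lowers RD1 and lengthens REM time / total sleep
#' time, and a responder subgroup whose probability of response rises with
#' baseline RD1.
#'
#' @param n_trd,n_hv Group sizes. Defaults 63 and 41.
#' @param n_responders Expected number of treatment responders among the TRD
#'   subjects with observed response data. Default 20.
#' @param n_missing_response TRD subjects whose day-1 depression score is
#'   missing (excluded from prediction). Default 2.
#' @param in_bed_min Lights-out to lights-on span, minutes. Default 480.
#' @param latency_mean Named vector of group REM-latency means (minutes),
#'   `c(TRD = 70, HV = 84)`; treatment leaves latency unchanged.
#' @param latency_sd Between-night REM-latency SD, minutes. Default 16.
#' @param onset_latency_mean Sleep-onset latency means (minutes) by night:
#'   `c(baseline = 22, post_treatment = 12)` (HV uses the baseline value).
#' @param rem_episode_min Mean REM-episode durations by cycle, minutes.
#' @param rem_treatment_factor Multiplier on REM-episode durations after
#'   treatment. Default 1.18.
#' @param rem_fragmentation_prob Probability that an interior epoch of a REM
#'   episode is a brief stage-2 interruption, which is what keeps REM
#'   efficiency below 100%. Default 0.05.
#' @param nrem_mean,nrem_sd Inter-REM NREM block duration (minutes); blocks
#'   are floored at 16 min so distinct episodes segment as distinct periods.
#' @param sws_cycle_min Mean slow-wave minutes inserted into successive NREM
#'   blocks.
#' @param wake_intrusion_prob Per-NREM-epoch probability of a wake
#'   intrusion, by night: `c(baseline = 0.12, post_treatment = 0.10)`.
#' @param terminal_wake_mean Mean terminal wake (minutes) by night:
#'   `c(baseline = 30, post_treatment = 18)`.
#' @param em_rate_mean Night-average eye-movement rate per REM minute; the
#'   same distribution for both groups. Default 1.2.
#' @param em_rate_cv Between-subject coefficient of variation of the rate
#'   (lognormal). Default 0.5.
#' @param first_period_mult First-REM-period rate multipliers,
#'   `c(TRD = 1.35, HV = 0.70)`; late-night rates are compensated so the
#'   night-average rate is unchanged.
#' @param treatment_rd1_factor Multiplier applied to the TRD first-period
#'   multiplier after treatment. Default 0.70.
#' @param em_amplitude_mean,em_amplitude_sd Eye-movement deflection
#'   amplitude distribution (microvolts), truncated above the 25 uV
#'   detection criterion.
#' @param hamd_mean,hamd_sd,hamd_floor Baseline HAM-D distribution: normal,
#'   truncated at the inclusion floor. Defaults 21.45, 3.98, 17.
#' @param response_link_slope Log-odds of response per unit baseline RD1
#'   (counts/min); the intercept is calibrated per cohort so the expected
#'   responder count equals `n_responders`. Default 1.5; 0 gives a null
#'   cohort for the prediction harness.
#' @param group_effects When `FALSE`, all group and treatment effects are
#'   switched off (equal latency means, unit multipliers, slope 0): the null
#'   configuration for calibration checks.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_trd = 63, n_hv = 41, n_responders = 20,
                        n_missing_response = 2, in_bed_min = 480,
                        latency_mean = c(TRD = 70, HV = 84), latency_sd = 16,
                        onset_latency_mean = c(baseline = 22, post_treatment = 12),
                        rem_episode_min = c(10, 14, 19, 23, 25, 25),
                        rem_treatment_factor = 1.18,
                        rem_fragmentation_prob = 0.05,
                        nrem_mean = 52, nrem_sd = 8,
                        sws_cycle_min = c(14, 8, 3, 0, 0, 0),
                        wake_intrusion_prob = c(baseline = 0.12, post_treatment = 0.10),
                        terminal_wake_mean = c(baseline = 30, post_treatment = 18),
                        em_rate_mean = 1.2, em_rate_cv = 0.5,
                        first_period_mult = c(TRD = 1.35, HV = 0.70),
                        treatment_rd1_factor = 0.70,
                        em_amplitude_mean = 45, em_amplitude_sd = 10,
                        hamd_mean = 21.45, hamd_sd = 3.98, hamd_floor = 17,
                        response_link_slope = 1.5,
                        group_effects = TRUE) {
  stopifnot(n_trd >= 1, n_hv >= 1, n_responders <= n_trd - n_missing_response,
            em_rate_mean >= 0, in_bed_min > 0)
  if (!group_effects) {
    latency_mean[] <- mean(latency_mean)
    first_period_mult[] <- 1
    treatment_rd1_factor <- 1
    rem_treatment_factor <- 1
    onset_latency_mean[] <- mean(onset_latency_mean)
    wake_intrusion_prob[] <- mean(wake_intrusion_prob)
    terminal_wake_mean[] <- mean(terminal_wake_mean)
    response_link_slope <- 0
  }
  structure(as.list(environment()), class = "cohort_spec")
}

# gamma draw parameterized by mean and sd, guarded for mean ~ 0
.rgamma_ms <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Simulate one night's hypnogram
#'
#' Semi-Markov night structure: a wake run until sleep onset, then
#' alternating NREM and REM blocks. The first NREM block's duration is the
#' night's REM latency, drawn from the group latency distribution; later
#' NREM blocks are at least 16 min long so that consecutive REM episodes
#' always segment as distinct REM periods; REM episodes lengthen across
#' cycles. Slow-wave epochs are embedded in the early NREM blocks, wake
#' intrusions are sprinkled over stage-2 epochs, and a terminal wake run
#' closes the record at the in-bed span.
#'
#' @param spec A [cohort_spec()].
#' @param group `"TRD"` or `"HV"`.
#' @param night `"baseline"` or `"post_treatment"`.
#' @param subject_id Subject identifier for the returned object.
#' @param rl_minutes Optional fixed REM latency (minutes); drawn from the
#'   group model when `NULL`.
#' @return A [hypnogram()]. Uses the session RNG; seed via [set.seed()].
#' @export
simulate_hypnogram <- function(spec, group = c("TRD", "HV"),
                               night = c("baseline", "post_treatment"),
                               subject_id = "sim", rl_minutes = NULL) {
  group <- match.arg(group)
  night <- match.arg(night)
  n_epochs <- as.integer(round(spec$in_bed_min * 2))
  stages <- rep("W", n_epochs)

  onset_lat <- .rgamma_ms(1, spec$onset_latency_mean[[night]], 6)
  onset_ep <- max(2L, round(onset_lat * 2))
  if (is.null(rl_minutes)) {
    rl_minutes <- .rgamma_ms(1, spec$latency_mean[[group]], spec$latency_sd)
  }
  rl_ep <- max(10L, round(rl_minutes * 2))

  terminal_ep <- max(0L, round(2 * .rgamma_ms(1, spec$terminal_wake_mean[[night]], 8)))
  sleep_end <- n_epochs - terminal_ep

  rem_factor <- if (night == "post_treatment") spec$rem_treatment_factor else 1
  pos <- onset_ep + 1L
  cycle <- 0L
  while (pos <= sleep_end) {
    cycle <- cycle + 1L
    nrem_ep <- if (cycle == 1L) {
      rl_ep
    } else {
      max(32L, round(2 * .rgamma_ms(1, spec$nrem_mean, spec$nrem_sd)))
    }
    nrem_ep <- min(nrem_ep, sleep_end - pos + 1L)
    if (nrem_ep > 0) {
      block <- rep("S2", nrem_ep)
      sws_mean <- if (cycle <= length(spec$sws_cycle_min)) {
        spec$sws_cycle_min[cycle]
      } else 0
      sws_ep <- min(round(2 * .rgamma_ms(1, sws_mean, max(sws_mean / 2, 1e-9))),
                    nrem_ep - 2L)
      if (sws_ep > 0) {
        at <- floor((nrem_ep - sws_ep) / 2) + seq_len(sws_ep)
        block[at] <- rep(c("S4", "S3"), length.out = sws_ep)
      }
      stages[pos:(pos + nrem_ep - 1L)] <- block
      pos <- pos + nrem_ep
    }
    if (pos > sleep_end) break
    rem_mean <- spec$rem_episode_min[min(cycle, length(spec$rem_episode_min))]
    rem_ep <- max(7L, round(2 * rem_factor * .rgamma_ms(1, rem_mean, 0.3 * rem_mean)))
    rem_ep <- min(rem_ep, sleep_end - pos + 1L)
    if (rem_ep > 0) {
      stages[pos:(pos + rem_ep - 1L)] <- "REM"
      pos <- pos + rem_ep
    }
  }

  # brief NREM interruptions inside REM episodes (interior epochs only, so
  # episode boundaries and the 15-min separation structure are unchanged)
  if (spec$rem_fragmentation_prob > 0) {
    r <- rle(stages)
    ends <- cumsum(r$lengths)
    for (j in which(r$values == "REM" & r$lengths > 2)) {
      interior <- (ends[j] - r$lengths[j] + 2L):(ends[j] - 1L)
      frag <- interior[stats::runif(length(interior)) < spec$rem_fragmentation_prob]
      stages[frag] <- "S2"
    }
  }

  # wake intrusions on stage-2 epochs only; REM episodes and SWS stay intact
  s2 <- which(stages == "S2")
  if (length(s2) > 1) {
    p <- spec$wake_intrusion_prob[[night]]
    flip <- s2[stats::runif(length(s2)) < p]
    flip <- setdiff(flip, s2[1])   # keep the onset-defining first S2 epoch
    stages[flip] <- "W"
  }
  hypnogram(stages, subject_id = subject_id, night = night)
}

#' Simulate eye-movement events for a night
#'
#' Homogeneous Poisson event trains within REM epochs. The rate in the first
#' segmented REM period is `base_rate * first_mult`; the rate over the rest
#' of the night's REM sleep is compensated so the expected night-average
#' rate stays `base_rate` (this is what lets first-period density differ
#' between groups while total-night density does not).
#'
#' @param hyp A [hypnogram()].
#' @param base_rate Night-average eye movements per REM minute.
#' @param first_mult First-REM-period rate multiplier. Default 1.
#' @param spec A [cohort_spec()] (amplitude distribution).
#' @return Event data frame (`time_s`, `amplitude_uv`, `channel`) plus
#'   attribute `"rates"` recording the first-period and late rates used.
#' @export
simulate_em_events <- function(hyp, base_rate, first_mult = 1,
                               spec = cohort_spec()) {
  periods <- segment_rem_periods(hyp)
  w <- .analysis_window(hyp)
  rem_ep <- w[hyp$stages[w] == "REM"]
  if (!length(rem_ep) || base_rate <= 0) {
    out <- .empty_events()
    attr(out, "rates") <- c(first = 0, late = 0)
    return(out)
  }
  t_total <- 0.5 * length(rem_ep)
  if (nrow(periods)) {
    p1 <- seq.int(periods$start[1], periods$end[1] - 1L)
    first_ep <- intersect(rem_ep, p1[hyp$stages[p1] == "REM"])
  } else {
    first_ep <- integer(0)
  }
  t1 <- 0.5 * length(first_ep)
  rate_first <- base_rate * first_mult
  rate_late <- if (t_total > t1) {
    max(0, base_rate * (t_total - first_mult * t1) / (t_total - t1))
  } else {
    rate_first
  }
  rates <- ifelse(rem_ep %in% first_ep, rate_first, rate_late)
  k <- stats::rpois(length(rem_ep), rates * 0.5)
  n <- sum(k)
  if (n == 0) {
    out <- .empty_events()
  } else {
    starts <- (rem_ep - 1L) * 30
    t_s <- rep(starts, k) + stats::runif(n) * 30
    amp <- 25.5 + .rgamma_ms(n, spec$em_amplitude_mean - 25.5,
                             spec$em_amplitude_sd)
    out <- data.frame(time_s = t_s, amplitude_uv = amp, channel = "LOC",
                      stringsAsFactors = FALSE)
    out <- out[order(out$time_s), ]
    rownames(out) <- NULL
  }
  attr(out, "rates") <- c(first = rate_first, late = rate_late)
  out
}

#' Render events as a synthetic two-channel EOG recording
#'
#' Each event becomes one biphasic (single-cycle sine) deflection whose
#' peak-to-trough excursion equals the event amplitude, mirrored with
#' opposite polarity on the two channels as a conjugate saccade would be,
#' plus independent Gaussian noise per channel. The input table is the
#' ground truth for detector recall/precision experiments.
#'
#' @param events Event data frame (`time_s`, `amplitude_uv`).
#' @param duration_s Trace duration, seconds.
#' @param sampling_rate Hz. Default 200.
#' @param noise_sd Gaussian noise SD, microvolts. Default 3.
#' @param deflection_s Deflection width, seconds. Default 0.5.
#' @return List with `loc`, `roc` ([eog_trace()] objects) and `truth` (the
#'   event table).
#' @export
simulate_eog <- function(events, duration_s, sampling_rate = 200,
                         noise_sd = 3, deflection_s = 0.5) {
  n <- round(duration_s * sampling_rate)
  base <- numeric(n)
  if (nrow(events)) {
    if (any(events$time_s < 0 | events$time_s > duration_s - deflection_s)) {
      stop("event times must fit within the trace span")
    }
    wl <- round(deflection_s * sampling_rate)
    wave <- sin(2 * pi * seq(0, deflection_s, length.out = wl) / deflection_s)
    for (i in seq_len(nrow(events))) {
      at <- round(events$time_s[i] * sampling_rate) + 1L
      idx <- at:(at + wl - 1L)
      base[idx] <- base[idx] + events$amplitude_uv[i] / 2 * wave
    }
  }
  noise <- function() if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  list(loc = eog_trace(base + noise(), sampling_rate, "LOC"),
       roc = eog_trace(-base + noise(), sampling_rate, "ROC"),
       truth = events)
}

#' Simulate clinical scores and responder labels
#'
#' Baseline HAM-D scores are drawn from a normal distribution truncated at
#' the study's inclusion floor. The probability of response rises with
#' baseline RD1 through a logistic link whose intercept is calibrated (by
#' root finding) so the expected responder count matches the spec; day-1
#' scores are then drawn consistently with each subject's responder status
#' under the inclusive 50%-reduction rule. A fixed number of subjects have
#' a missing day-1 score.
#'
#' @param spec A [cohort_spec()].
#' @param rd1_baseline Baseline RD1 values of the treated subjects
#'   (counts/min; `NA` tolerated and treated as the group mean for the
#'   link).
#' @return Data frame: `hamd_baseline`, `hamd_day1`, `responder` (logical,
#'   `NA` where day-1 is missing).
#' @export
simulate_clinical <- function(spec, rd1_baseline) {
  n <- length(rd1_baseline)
  x <- rd1_baseline
  x[!is.finite(x)] <- mean(x, na.rm = TRUE)
  hamd0 <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, spec$hamd_mean, spec$hamd_sd)
      if (v >= spec$hamd_floor) break
    }
    hamd0[i] <- round(v)
  }
  miss <- if (spec$n_missing_response > 0) {
    sample.int(n, spec$n_missing_response)
  } else {
    integer(0)
  }
  obs <- setdiff(seq_len(n), miss)
  b <- spec$response_link_slope
  target <- spec$n_responders
  f <- function(a) sum(stats::plogis(a + b * x[obs])) - target
  a <- stats::uniroot(f, c(-60, 60))$root
  responder <- rep(NA, n)
  responder[obs] <- stats::runif(length(obs)) < stats::plogis(a + b * x[obs])
  hamd1 <- rep(NA_real_, n)
  for (i in obs) {
    if (responder[i]) {
      red <- stats::runif(1, 0.5, 0.85)
      hamd1[i] <- floor(hamd0[i] * (1 - red))
    } else {
      red <- stats::runif(1, 0.0, 0.45)
      hamd1[i] <- ceiling(hamd0[i] * (1 - red))
    }
  }
  data.frame(hamd_baseline = hamd0, hamd_day1 = hamd1,
             responder = as.logical(responder))
}

#' Simulate a full cohort and compute its metric table
#'
#' Draws per-subject night-average eye-movement rates (shared across a
#' subject's nights, which is what gives the paired treatment contrast its
#' within-subject correlation), simulates hypnograms and event trains for
#' every subject-night (TRD: baseline and post-treatment; HV: baseline),
#' runs the full metric pipeline on each night, and attaches simulated
#' clinical scores and responder labels for the TRD group.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed for exact regeneration.
#' @return A data frame of class `"cohort_table"`: one row per subject-night
#'   with `subject_id`, `group`, `night`, the ten night metrics,
#'   `hamd_baseline`, `hamd_day1`, `responder`. Attributes: `spec`, `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + spec$em_rate_cv^2))
  meanlog <- log(spec$em_rate_mean) - sdlog^2 / 2

  one_night <- function(id, group, night, base_rate) {
    mult <- spec$first_period_mult[[group]]
    if (group == "TRD" && night == "post_treatment") {
      mult <- mult * spec$treatment_rd1_factor
    }
    hyp <- simulate_hypnogram(spec, group, night, subject_id = id)
    ev <- simulate_em_events(hyp, base_rate, mult, spec)
    counts <- count_events_by_epoch(ev, hyp, dedup_window_s = 0)
    night_metrics(hyp, counts)
  }

  rows <- list()
  for (i in seq_len(spec$n_trd)) {
    id <- sprintf("TRD%03d", i)
    rate <- stats::rlnorm(1, meanlog, sdlog)
    rows[[length(rows) + 1L]] <- cbind(one_night(id, "TRD", "baseline", rate),
                                       group = "TRD")
    rows[[length(rows) + 1L]] <- cbind(one_night(id, "TRD", "post_treatment", rate),
                                       group = "TRD")
  }
  for (i in seq_len(spec$n_hv)) {
    id <- sprintf("HV%03d", i)
    rate <- stats::rlnorm(1, meanlog, sdlog)
    rows[[length(rows) + 1L]] <- cbind(one_night(id, "HV", "baseline", rate),
                                       group = "HV")
  }
  cohort <- do.call(rbind, rows)

  trd_base <- cohort$group == "TRD" & cohort$night == "baseline"
  clin <- simulate_clinical(spec, cohort$rd1[trd_base])
  clin_id <- cohort$subject_id[trd_base]
  m <- match(cohort$subject_id, clin_id)
  cohort$hamd_baseline <- clin$hamd_baseline[m]
  cohort$hamd_day1 <- clin$hamd_day1[m]
  cohort$responder <- clin$responder[m]
  rownames(cohort) <- NULL
  structure(cohort, spec = spec, seed = seed,
            class = c("cohort_table", "data.frame"))
}
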