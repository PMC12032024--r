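#' Read a hypnogram CSV
#'
#' The dialect is a two-column CSV with header `epoch,stage` (0-based epoch
#' index, stage token) preceded by comment lines of the form
#' `#key=value`; `#lights_out=HH:MM:SS` and `#lights_on=HH:MM:SS` carry the
#' clock anchors, `#subject_id=` and `#night=` are honored when present.
#' Stage tokens are translated through `stage_map`, so both classical
#' (S1--S4) and AASM (N1--N3, R) files load.
#'
#' @param path File path.
#' @param stage_map Named translation vector; see [default_stage_map()].
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, stage_map = default_stage_map()) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  meta <- list()
  for (cl in sub("^#", "", lines[is_comment])) {
    kv <- strsplit(cl, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!is_comment]
  if (!length(body)) stop("no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = c("integer", "character"))
  if (!all(c("epoch", "stage") %in% names(df))) {
    stop("hypnogram file must have columns epoch,stage: ", path)
  }
  df <- df[order(df$epoch), ]
  if (!identical(df$epoch, seq_len(nrow(df)) - 1L)) {
    stop("epoch column must be the contiguous 0-based sequence: ", path)
  }
  tok <- toupper(trimws(df$stage))
  mapped <- unname(stage_map[tok])
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))
    stop("unknown stage token(s) in ", path, " at epoch(s): ",
         paste(utils::head(df$epoch[bad], 10L), collapse = ", "),
         " [", paste(unique(tok[bad]), collapse = ", "), "]")
  }
  if (is.null(meta$lights_out)) stop("missing #lights_out= header in ", path)
  hypnogram(mapped,
            subject_id = meta$subject_id %||% basename(path),
            night = meta$night %||% "baseline",
            lights_out = meta$lights_out,
            lights_on = meta$lights_on)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hypnogram CSV
#'
#' Inverse of [read_hypnogram()]; round-trips exactly.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#subject_id=%s", hyp$subject_id),
               sprintf("#night=%s", hyp$night),
               sprintf("#lights_out=%s", hyp$lights_out),
               sprintf("#lights_on=%s", hyp$lights_on),
               "epoch,stage",
               sprintf("%d,%s", seq_along(hyp$stages) - 1L, hyp$stages)), con)
  invisible(path)
}

#' Read a pre-detected eye-movement event table
#'
#' CSV with columns `time_s,amplitude_uv,channel`. Supplying such a table
#' bypasses the detector; densities computed either way are identical.
#'
#' @param path File path.
#' @return Event data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "amplitude_uv", "channel")
  if (!all(need %in% names(df))) {
    stop("event file must have columns ", paste(need, collapse = ","))
  }
  df[, need]
}

#' Read a clinical table
#'
#' CSV with columns `subject_id,group,hamd_baseline,hamd_day1` (empty
#' `hamd_day1` = missing).
#'
#' @param path File path.
#' @return Data frame with a derived logical `responder` column
#'   ([label_responders()], `NA` for healthy volunteers and missing scores).
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "group", "hamd_baseline", "hamd_day1")
  if (!all(need %in% names(df))) {
    stop("clinical file must have columns ", paste(need, collapse = ","))
  }
  df$responder <- ifelse(df$group == "TRD",
                         label_responders(df$hamd_baseline, df$hamd_day1), NA)
  df
}

#' Analysis run configuration
#'
#' Collects every defaulted decision of the pipeline in one serializable
#' object: detector settings, segmentation flags, the statistical families,
#' the prediction configuration and the synthetic-cohort spec.
#'
#' @param spec [cohort_spec()] for simulated input.
#' @param seed Master seed for the run.
#' @param alpha Family-wise significance level. Default 0.05.
#' @param detector Detector settings (threshold, refractory, band,
#'   binocular window).
#' @param segmentation Segmentation settings (minimum REM minutes,
#'   separating gap, whether wake counts toward gaps).
#' @param family_markers,family_architecture The two Holm families: the REM
#'   marker trio and the architecture panel.
#' @param prediction Prediction-harness settings (iterations, train
#'   fraction, SVM cost, response scale and threshold).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(spec = cohort_spec(), seed = 20260930, alpha = 0.05,
                       detector = list(threshold_uv = 25, refractory_s = 0.1,
                                       band_hz = c(0.3, 10),
                                       dedup_window_s = 0.2),
                       segmentation = list(min_rem_min = 3, gap_min = 15,
                                           gap_counts_wake = TRUE,
                                           numerator_rem_only = TRUE),
                       family_markers = c("rl_minutes", "rd1", "total_night_rd"),
                       family_architecture = c("tst", "sws", "waso", "rem_time",
                                               "rem_percent", "rem_efficiency",
                                               "rl_minutes", "se"),
                       prediction = list(n_iterations = 1000,
                                         train_fraction = 0.70, cost = 1,
                                         response_scale = "HAMD",
                                         response_threshold = 0.50)) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the three study analyses on a cohort
#'
#' Given a cohort table (simulated via [simulate_cohort()] when `cohort` is
#' `NULL`), runs (1) the baseline group comparison of the REM marker trio
#' (REM latency, RD1, total-night REM density; Mann-Whitney U, Holm
#' corrected), (2) the paired treatment contrasts of the marker trio and of
#' the architecture panel (Wilcoxon signed-rank, Holm corrected per
#' family), and (3) the RD1-based responder prediction harness. Analyses
#' whose inputs are absent (e.g. no post-treatment nights) are skipped with
#' the reason recorded.
#'
#' @param config A [run_config()].
#' @param cohort Optional cohort table; simulated from `config$spec` and
#'   `config$seed` when `NULL`.
#' @return List of class `"analysis_bundle"`: `summary` (mean +/- SEM
#'   table), `group_tests`, `treatment_tests`, `prediction`
#'   (a `prediction_report` or `NULL`), `skipped` (named reasons),
#'   `config`, `seed`.
#' @export
run_analysis <- function(config = run_config(), cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$spec, seed = config$seed)
  }
  skipped <- list()
  metrics_all <- unique(c(config$family_markers, config$family_architecture))
  summ <- summary_table(cohort, metrics_all)

  group_tests <- NULL
  if (all(c("TRD", "HV") %in% cohort$group)) {
    group_tests <- do.call(rbind, lapply(config$family_markers, function(m) {
      compare_groups(cohort, m, night = "baseline")
    }))
    adj <- holm_adjust(group_tests$p, config$alpha)
    group_tests$p_adjusted <- adj$p_adjusted
    group_tests$significant <- adj$significant
  } else {
    skipped$group_tests <- "both groups required for the baseline comparison"
  }

  treatment_tests <- NULL
  if ("post_treatment" %in% cohort$night) {
    fam <- function(metrics) {
      tt <- do.call(rbind, lapply(metrics, function(m) {
        compare_paired(cohort, m)
      }))
      adj <- holm_adjust(tt$p, config$alpha)
      tt$p_adjusted <- adj$p_adjusted
      tt$significant <- adj$significant
      tt
    }
    treatment_tests <- list(markers = fam(config$family_markers),
                            architecture = fam(config$family_architecture))
  } else {
    skipped$treatment_tests <- "no post-treatment nights in cohort"
  }

  prediction <- NULL
  base <- cohort[cohort$night == "baseline" & cohort$group == "TRD", ]
  ok <- !is.na(base$responder) & is.finite(base$rd1)
  if (sum(base$responder[ok]) >= 2 && sum(!base$responder[ok]) >= 2) {
    prediction <- holdout_validate(
      base$rd1[ok], base$responder[ok],
      n_iterations = config$prediction$n_iterations,
      train_fraction = config$prediction$train_fraction,
      cost = config$prediction$cost,
      seed = config$seed + 1L)
  } else {
    skipped$prediction <- "need >= 2 responders and >= 2 non-responders with RD1"
  }

  structure(list(summary = summ, group_tests = group_tests,
                 treatment_tests = treatment_tests, prediction = prediction,
                 skipped = skipped, config = config, seed = config$seed),
            class = "analysis_bundle")
}

#' Write an analysis bundle to a directory
#'
#' Emits `summary.csv`, `group_tests.csv`, `treatment_markers.csv`,
#' `treatment_architecture.csv`, `prediction.json`, `roc.csv` and
#' `manifest.json` (config, seed and skip reasons -- enough to regenerate
#' the bundle exactly).
#'
#' @param bundle An [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$group_tests)) {
    utils::write.csv(bundle$group_tests, file.path(dir, "group_tests.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$treatment_tests)) {
    utils::write.csv(bundle$treatment_tests$markers,
                     file.path(dir, "treatment_markers.csv"), row.names = FALSE)
    utils::write.csv(bundle$treatment_tests$architecture,
                     file.path(dir, "treatment_architecture.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$prediction)) {
    p <- bundle$prediction
    jsonlite::write_json(
      list(median_accuracy = p$median_accuracy,
           accuracy_ci = as.numeric(p$accuracy_ci), auc = p$auc,
           mean_tpr_pct = p$mean_tpr_pct, mean_fpr_pct = p$mean_fpr_pct,
           config = p$config),
      file.path(dir, "prediction.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    utils::write.csv(p$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = bundle$seed, alpha = bundle$config$alpha,
         detector = bundle$config$detector,
         segmentation = bundle$config$segmentation,
         families = list(markers = bundle$config$family_markers,
                         architecture = bundle$config$family_architecture),
         prediction = bundle$config$prediction,
         spec = unclass(bundle$config$spec),
         skipped = bundle$skipped),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
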