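# Independent brute-force oracles used across the suite. Deliberately naive:
# epoch-by-epoch scans and enumeration, sharing no code with the package.

# Naive REM-period segmentation: walk the stage string left to right,
# accumulating REM epochs into the current candidate; a stretch of >= gap_min
# qualifying minutes between REM epochs closes the candidate. Then drop
# candidates under min_rem_min and flag completion by scanning forward.
oracle_segment <- function(stages, min_rem_min = 3, gap_min = 15,
                           gap_counts_wake = TRUE) {
  gap_needed <- gap_min * 2
  counts_gap <- function(st) {
    if (gap_counts_wake) st != "REM" else st %in% c("S1", "S2", "S3", "S4")
  }
  cands <- list()
  cur <- integer(0)
  gap_run <- 0
  for (i in seq_along(stages)) {
    if (stages[i] == "REM") {
      if (length(cur) && gap_run >= gap_needed) {
        cands[[length(cands) + 1L]] <- cur
        cur <- integer(0)
      }
      cur <- c(cur, i)
      gap_run <- 0
    } else if (counts_gap(stages[i])) {
      gap_run <- gap_run + 1
    }
  }
  if (length(cur)) cands[[length(cands) + 1L]] <- cur
  cands <- Filter(function(ix) 0.5 * length(ix) >= min_rem_min, cands)
  sleep_idx <- which(stages %in% c("S1", "S2", "S3", "S4", "REM"))
  fw <- if (length(sleep_idx)) max(sleep_idx) + 1L else NA_integer_
  rem_all <- which(stages == "REM")
  rows <- lapply(cands, function(ix) {
    e <- max(ix) + 1L
    nxt <- rem_all[rem_all >= e]
    stop_at <- if (length(nxt)) min(min(nxt), fw) else fw
    qual <- 0
    if (!is.na(fw) && stop_at > e) {
      for (k in e:(stop_at - 1L)) if (counts_gap(stages[k])) qual <- qual + 1
    }
    data.frame(start = min(ix), end = e, rem_minutes = 0.5 * length(ix),
               span_minutes = 0.5 * (e - min(ix)), completed = qual >= gap_needed)
  })
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      rem_minutes = numeric(0), span_minutes = numeric(0),
                      completed = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Naive per-night metric recount via explicit epoch loops.
oracle_metrics <- function(stages, counts = NULL) {
  sleep <- c("S1", "S2", "S3", "S4", "REM")
  onset <- NA_integer_
  for (i in seq_along(stages)) if (stages[i] == "S2") { onset <- i; break }
  fw <- NA_integer_
  for (i in rev(seq_along(stages))) if (stages[i] %in% sleep) { fw <- i + 1L; break }
  n_sleep <- n_sws <- n_w <- n_rem <- 0
  if (!is.na(onset)) {
    for (i in onset:(fw - 1L)) {
      st <- stages[i]
      if (st %in% sleep) n_sleep <- n_sleep + 1
      if (st %in% c("S3", "S4")) n_sws <- n_sws + 1
      if (st == "W") n_w <- n_w + 1
      if (st == "REM") n_rem <- n_rem + 1
    }
  }
  tst <- if (is.na(onset)) NA_real_ else 0.5 * n_sleep
  segs <- oracle_segment(stages)
  rl <- if (is.na(onset) || !nrow(segs)) NA_real_ else 0.5 * (segs$start[1] - onset)
  rt <- if (is.na(onset)) NA_real_ else 0.5 * n_rem
  rp <- if (is.na(tst) || tst <= 0) NA_real_ else 100 * rt / tst
  comp <- segs[segs$completed, , drop = FALSE]
  reff <- if (nrow(comp)) 100 * sum(comp$rem_minutes) / sum(comp$span_minutes) else NA_real_
  trd <- rd1v <- NA_real_
  if (!is.null(counts)) {
    if (!is.na(rt) && rt > 0) {
      s <- 0
      for (i in onset:(fw - 1L)) if (stages[i] == "REM") s <- s + counts[i]
      trd <- s / rt
    }
    if (nrow(segs)) {
      s <- 0
      for (i in segs$start[1]:(segs$end[1] - 1L)) {
        if (stages[i] == "REM") s <- s + counts[i]
      }
      rd1v <- s / segs$rem_minutes[1]
    }
  }
  list(rl_minutes = rl, rd1 = rd1v, total_night_rd = trd, tst = tst,
       rem_time = rt, rem_percent = rp, rem_efficiency = reff,
       sws = if (is.na(onset)) NA_real_ else 0.5 * n_sws,
       waso = if (is.na(onset)) NA_real_ else 0.5 * n_w,
       se = 100 * 0.5 * sum(stages %in% sleep) / (0.5 * length(stages)))
}

# Random scored night for oracle-equivalence checks: unstructured stage soup
# (includes degenerate patterns no generator would emit).
random_stages <- function(n = 600) {
  sample(c("W", "S1", "S2", "S3", "S4", "REM", "UNSCORED"), n, replace = TRUE,
         prob = c(0.12, 0.06, 0.38, 0.09, 0.06, 0.25, 0.04))
}

# Exact two-tailed Mann-Whitney p by enumeration over all group assignments
# (doubled smaller tail, as wilcox.test defines it).
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exact two-tailed Wilcoxon signed-rank p by enumeration over sign patterns.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# AUC via the Mann-Whitney rank identity (midranks).
oracle_auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small cohort table wrapper for statistical-workflow tests.
toy_cohort <- function(trd, hv, metric = "m") {
  out <- data.frame(
    subject_id = c(sprintf("T%03d", seq_along(trd)), sprintf("H%03d", seq_along(hv))),
    group = c(rep("TRD", length(trd)), rep("HV", length(hv))),
    night = "baseline")
  out[[metric]] <- c(trd, hv)
  out
}

toy_paired_cohort <- function(baseline, post, metric = "m") {
  n <- length(baseline)
  out <- data.frame(
    subject_id = rep(sprintf("T%03d", seq_len(n)), 2),
    group = "TRD",
    night = rep(c("baseline", "post_treatment"), each = n))
  out[[metric]] <- c(baseline, post)
  out
}
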