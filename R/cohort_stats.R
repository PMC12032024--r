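#' Shapiro-Wilk normality gate
#'
#' Advisory normality check applied before the non-parametric workflow; the
#' pipeline always proceeds non-parametrically regardless of the outcome,
#' the gate simply documents the distributional evidence.
#'
#' @param x Numeric sample (NAs dropped), `n >= 3`.
#' @return A list with `n`, `W`, `p`, and `degenerate` (`TRUE` for a constant
#'   sample, in which case `W`/`p` are `NA`).
#' @export
normality_gate <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("normality gate needs at least 3 observations")
  if (length(unique(x)) == 1L) {
    return(list(n = length(x), W = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  if (length(x) > 5000) x <- x[seq_len(5000)]  # shapiro.test hard limit
  sw <- stats::shapiro.test(x)
  list(n = length(x), W = unname(sw$statistic), p = sw$p.value,
       degenerate = FALSE)
}

# Two-tailed Mann-Whitney U test. p-value from stats::wilcox.test (exact when
# both groups <= `exact_max` with no ties, else normal approximation with
# continuity correction); the normal-approximation Z with tie correction is
# reported alongside, as is the rank-biserial correlation whose sign gives
# the direction of the difference (positive: x tends larger).
.mwu <- function(x, y, exact_max = 20) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- n1 <= exact_max && n2 <= exact_max && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  U <- unname(wt$statistic)               # U for x over y
  N <- n1 + n2
  mu <- n1 * n2 / 2
  r <- rank(c(x, y))
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2) else 0
  list(statistic = U, z = z, p = wt$p.value,
       rank_biserial = 2 * U / (n1 * n2) - 1, n1 = n1, n2 = n2,
       exact = use_exact)
}

# Two-tailed Wilcoxon signed-rank test on paired differences. Zero
# differences are dropped before ranking (Wilcoxon's treatment); when all
# differences are zero the result is the no-effect value p = 1, z = 0.
.wsr <- function(x, y, exact_max = 25) {
  d <- x - y
  d <- d[is.finite(d)]
  if (!length(d)) stop("no paired observations")
  d <- d[d != 0]
  if (!length(d)) {
    return(list(statistic = NA_real_, z = 0, p = 1, n = 0, exact = FALSE))
  }
  n <- length(d)
  has_ties <- anyDuplicated(abs(d)) > 0
  use_exact <- n <= exact_max && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = TRUE))
  V <- unname(wt$statistic)
  mu <- n * (n + 1) / 4
  r <- rank(abs(d))
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2) else 0
  list(statistic = V, z = z, p = wt$p.value, n = n, exact = use_exact)
}

.pick_metric <- function(cohort, metric, group = NULL, night = NULL) {
  sel <- rep(TRUE, nrow(cohort))
  if (!is.null(group)) sel <- sel & cohort$group == group
  if (!is.null(night)) sel <- sel & cohort$night == night
  cohort[[metric]][sel]
}

#' Compare a metric between groups with the Mann-Whitney U test
#'
#' Two-tailed independent-samples comparison of one night-metric between the
#' patient and control groups at a given night (baseline by default), as used
#' for the baseline REM-marker contrasts.
#'
#' @param cohort A cohort table (see [simulate_cohort()]): one row per
#'   subject-night with `group`, `night` and metric columns.
#' @param metric Name of the metric column.
#' @param night Night at which to compare. Default `"baseline"`.
#' @param groups Length-2 character vector naming the two groups; the first
#'   is reported as the reference for the direction sign.
#' @return A one-row data frame: `metric`, `test`, `statistic` (U), `z`, `p`,
#'   `n1`, `n2`, `direction` (rank-biserial correlation).
#' @export
compare_groups <- function(cohort, metric, night = "baseline",
                           groups = c("TRD", "HV")) {
  x <- .pick_metric(cohort, metric, group = groups[1], night = night)
  y <- .pick_metric(cohort, metric, group = groups[2], night = night)
  res <- .mwu(x, y)
  data.frame(metric = metric, test = "mann-whitney",
             statistic = res$statistic, z = res$z, p = res$p,
             n1 = res$n1, n2 = res$n2, direction = res$rank_biserial,
             stringsAsFactors = FALSE)
}

#' Compare a metric across nights with the Wilcoxon signed-rank test
#'
#' Two-tailed paired comparison of one metric between two nights of the same
#' subjects (baseline vs post-treatment by default), as used for the
#' treatment-effect contrasts. Only subjects observed on both nights with a
#' finite metric value on both contribute.
#'
#' @param cohort A cohort table.
#' @param metric Name of the metric column.
#' @param nights Length-2 character vector `(night1, night2)`; differences
#'   are `night1 - night2`.
#' @param group Restrict to one group (default `"TRD"`, the treated group).
#' @return A one-row data frame: `metric`, `test`, `statistic` (V), `z`, `p`,
#'   `n` (non-zero paired differences).
#' @export
compare_paired <- function(cohort, metric,
                           nights = c("baseline", "post_treatment"),
                           group = "TRD") {
  a <- cohort[cohort$group == group & cohort$night == nights[1],
              c("subject_id", metric)]
  b <- cohort[cohort$group == group & cohort$night == nights[2],
              c("subject_id", metric)]
  m <- merge(a, b, by = "subject_id", suffixes = c("_1", "_2"))
  if (!nrow(m)) stop("no subjects observed on both nights")
  res <- .wsr(m[[paste0(metric, "_1")]], m[[paste0(metric, "_2")]])
  data.frame(metric = metric, test = "wilcoxon-signed-rank",
             statistic = res$statistic, z = res$z, p = res$p, n = res$n,
             stringsAsFactors = FALSE)
}

#' Bonferroni-Holm adjustment of a p-value family
#'
#' Step-down Holm adjustment with reject/retain decisions at `alpha`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise error rate. Default 0.05.
#' @return Data frame with `p`, `p_adjusted`, `significant`, in input order.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value family")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, significant = adj <= alpha)
}

#' Mean +/- SEM summary table
#'
#' Per-metric, per-cell summaries in the layout of a clinical sleep table:
#' mean, standard error of the mean and n for every combination of the
#' grouping columns.
#'
#' @param cohort A cohort table.
#' @param metrics Character vector of metric column names.
#' @param by Grouping columns. Default `c("group", "night")`.
#' @return Data frame with one row per metric x cell: grouping columns,
#'   `metric`, `mean`, `sem` (`NA` for a single observation), `n`, and a
#'   preformatted `label` "mean (+/- sem)".
#' @export
summary_table <- function(cohort, metrics, by = c("group", "night")) {
  cells <- unique(cohort[, by, drop = FALSE])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(cohort))
    for (b in by) sel <- sel & cohort[[b]] == cells[[b]][i]
    do.call(rbind, lapply(metrics, function(m) {
      v <- cohort[[m]][sel]
      v <- v[is.finite(v)]
      n <- length(v)
      mu <- if (n) mean(v) else NA_real_
      sem <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
      cbind(cells[i, , drop = FALSE],
            data.frame(metric = m, mean = mu, sem = sem, n = n,
                       label = if (n) sprintf("%.2f (± %.2f)", mu, sem)
                               else "-",
                       stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
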