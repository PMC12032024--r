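#' Label antidepressant responders
#'
#' Response is defined as a reduction of at least `threshold` (default 50%)
#' of the baseline depression-scale score one day after treatment. The
#' boundary is inclusive: exactly a 50% reduction counts as response.
#'
#' @param baseline Baseline scale score(s), must be positive.
#' @param day1 Day-1 post-treatment score(s); `NA` propagates (subjects with
#'   missing response data are excluded upstream).
#' @param threshold Required fractional reduction. Default 0.5.
#' @return Logical vector; `NA` where either score is missing.
#' @export
label_responders <- function(baseline, day1, threshold = 0.5) {
  if (any(!is.na(baseline) & baseline <= 0)) {
    stop("baseline scores must be positive")
  }
  (baseline - day1) / baseline >= threshold
}

#' Empirical ROC curve and AUC from decision scores
#'
#' Threshold-sweep ROC on continuous decision scores (higher score = more
#' likely positive), with tied scores grouped so the curve takes the tie
#' diagonal; AUC by the trapezoidal rule, which under this tie handling is
#' identical to the normalized Mann-Whitney rank statistic.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical (or 0/1) class labels, `TRUE` = positive. Both
#'   classes must be present.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`, beginning
#'   at (0, 0)) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels),
            all(is.finite(scores)))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)       # index of last element of each tie group
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Summarize a hold-out accuracy distribution
#'
#' @param accuracies Per-iteration accuracies.
#' @return List with `median` and `ci` (2.5 and 97.5 percentiles).
#' @export
accuracy_summary <- function(accuracies) {
  stopifnot(length(accuracies) > 0)
  list(median = stats::median(accuracies),
       ci = unname(stats::quantile(accuracies, c(0.025, 0.975))))
}

# Stratified train indices: round(n_class * fraction) per class, at least one
# per class in both halves.
.stratified_train <- function(labels, fraction) {
  idx_pos <- which(labels); idx_neg <- which(!labels)
  k_pos <- min(max(1L, round(length(idx_pos) * fraction)), length(idx_pos) - 1L)
  k_neg <- min(max(1L, round(length(idx_neg) * fraction)), length(idx_neg) - 1L)
  c(sample(idx_pos, k_pos), sample(idx_neg, k_neg))
}

#' Repeated stratified hold-out validation of an RBF-kernel SVM
#'
#' Evaluates how well a feature panel (typically the single baseline RD1
#' value) separates responders from non-responders: `n_iterations` random
#' stratified splits (default 70% training / 30% test, class proportions
#' preserved to within one subject), feature standardization fit on the
#' training half only, a radial-basis-function support vector machine fit on
#' the training half, and accuracy / true-positive rate / false-positive
#' rate measured on the held-out third. Test-set decision scores are pooled
#' across all iterations into a single ROC curve and AUC; the per-iteration
#' AUC distribution is reported alongside.
#'
#' @param features Numeric vector or matrix of predictor values, one row per
#'   subject.
#' @param labels Logical responder labels, `TRUE` = responder; both classes
#'   need at least 2 members.
#' @param n_iterations Number of hold-out splits. Default 1000.
#' @param train_fraction Training proportion. Default 0.70.
#' @param cost SVM regularization constant C. Default 1.
#' @param gamma RBF kernel width; default `1/d` on standardized features
#'   (the data-scaled rule, since each standardized column has unit
#'   variance).
#' @param seed Optional integer seed; given the seed the full report is
#'   reproducible.
#' @return An object of class `"prediction_report"`: list with `iterations`
#'   (data frame `accuracy`, `tpr`, `fpr`, `auc`), `roc` (pooled ROC
#'   points), `auc` (pooled), `median_accuracy`, `accuracy_ci`,
#'   `mean_tpr_pct`, `mean_fpr_pct` (0--100 scale), and `config`.
#' @export
holdout_validate <- function(features, labels, n_iterations = 1000,
                             train_fraction = 0.70, cost = 1, gamma = NULL,
                             seed = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.logical(labels)
  keep <- stats::complete.cases(X) & !is.na(labels)
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  if (sum(labels) < 2 || sum(!labels) < 2) {
    stop("both classes need at least 2 members")
  }
  if (!all(is.finite(X))) stop("features must be finite")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant feature column")
  stopifnot(train_fraction > 0, train_fraction < 1, n_iterations >= 1)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (!is.null(seed)) set.seed(seed)

  y <- factor(ifelse(labels, "responder", "nonresponder"),
              levels = c("nonresponder", "responder"))
  it <- data.frame(accuracy = numeric(n_iterations), tpr = numeric(n_iterations),
                   fpr = numeric(n_iterations), auc = numeric(n_iterations))
  pool_scores <- vector("list", n_iterations)
  pool_labels <- vector("list", n_iterations)

  for (i in seq_len(n_iterations)) {
    tr <- .stratified_train(labels, train_fraction)
    te <- setdiff(seq_along(labels), tr)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- scale(X[tr, , drop = FALSE], center = mu, scale = sg)
    Zte <- scale(X[te, , drop = FALSE], center = mu, scale = sg)
    fit <- e1071::svm(x = Ztr, y = y[tr], kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, Zte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # e1071 orients decision values toward the first class in the column
    # name "A/B"; flip so larger score = responder
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    score <- if (identical(first, "responder")) dv[, 1] else -dv[, 1]
    truth <- labels[te]
    predicted <- pred == "responder"
    it$accuracy[i] <- mean(predicted == truth)
    it$tpr[i] <- if (any(truth)) mean(predicted[truth]) else NA_real_
    it$fpr[i] <- if (any(!truth)) mean(predicted[!truth]) else NA_real_
    it$auc[i] <- roc_and_auc(score, truth)$auc
    pool_scores[[i]] <- score
    pool_labels[[i]] <- truth
  }

  pooled <- roc_and_auc(unlist(pool_scores), unlist(pool_labels))
  acc <- accuracy_summary(it$accuracy)
  structure(list(
    iterations = it,
    roc = pooled$roc,
    auc = pooled$auc,
    median_accuracy = acc$median,
    accuracy_ci = acc$ci,
    mean_tpr_pct = 100 * mean(it$tpr, na.rm = TRUE),
    mean_fpr_pct = 100 * mean(it$fpr, na.rm = TRUE),
    config = list(n_iterations = n_iterations, train_fraction = train_fraction,
                  kernel = "rbf", cost = cost, gamma = gamma, seed = seed,
                  n = length(labels), n_responders = sum(labels))
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d iterations, %d subjects (%d responders)\n",
              x$config$n_iterations, x$config$n, x$config$n_responders))
  cat(sprintf("  median accuracy %.2f (95%% CI [%.2f; %.2f]), pooled AUC %.2f\n",
              x$median_accuracy, x$accuracy_ci[1], x$accuracy_ci[2], x$auc))
  cat(sprintf("  mean TPR %.2f, mean FPR %.2f (0-100 scale)\n",
              x$mean_tpr_pct, x$mean_fpr_pct))
  invisible(x)
}
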