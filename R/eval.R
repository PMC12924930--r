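## Model evaluation: ROC/AUC via the Mann-Whitney statistic, the
## clinical metric panel, DeLong's test for paired ROC curves,
## DeLong-variance confidence intervals, and the 100-point
## clinical/graph probability-ensemble weight scan.

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney probability: the mean over all
#' (positive, negative) pairs of \eqn{1[s^+ > s^-] + 0.5 \cdot 1[s^+ = s^-]}.
#' Computed from midranks, so ties are handled exactly.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement values: for each positive, the fraction of negatives
# it beats (ties count 1/2); symmetrically for negatives.
placement_values <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares AUCs of two score vectors computed on the same cases using
#' the DeLong placement-value (structural component) decomposition and
#' a two-sided normal approximation on
#' \eqn{\Delta AUC / \sqrt{var}}.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels shared by both.
#' @return list with `auc_a`, `auc_b`, `delta`, `variance`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  m <- length(pa$v10); n <- length(pa$v01)
  # variance of the AUC difference from paired structural components
  var_d <- stats::var(pa$v10 - pb$v10) / m + stats::var(pa$v01 - pb$v01) / n
  delta <- auc_a - auc_b
  if (var_d <= 0 || !is.finite(var_d)) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      p <- 1
    } else {
      warning("zero DeLong variance with nonzero AUC difference")
      p <- 0
    }
  } else {
    p <- 2 * stats::pnorm(-abs(delta) / sqrt(var_d))
  }
  list(auc_a = auc_a, auc_b = auc_b, delta = delta,
       variance = var_d, p_value = p)
}

#' DeLong-variance confidence interval for one AUC
#'
#' Normal interval on the AUC using the DeLong variance estimate,
#' truncated to `[0, 1]`. A degenerate (zero) variance collapses the
#' interval to the AUC point.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
auc_confidence_interval <- function(scores, labels, level = 0.95) {
  pv <- placement_values(scores, labels)
  auc <- mean(pv$v10)
  v <- stats::var(pv$v10) / length(pv$v10) + stats::var(pv$v01) / length(pv$v01)
  if (!is.finite(v) || v <= 0) return(c(auc, auc))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
}

#' Evaluation metric panel
#'
#' Confusion counts at `score >= threshold`, plus prevalence, accuracy,
#' precision, F1, sensitivity and specificity (the last two as
#' percentages), AUC and its confidence interval, and the ROC points.
#' Metrics with a zero denominator are `NA` with a warning.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `eval_report`.
#' @export
metric_panel <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  safe_div <- function(a, b, what) {
    if (b == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else a / b
  }
  precision <- safe_div(tp, tp + fp, "precision")
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  f1 <- if (is.na(precision) || is.na(sens) || precision + sens == 0) {
    NA_real_
  } else 2 * precision * sens / (precision + sens)
  thr_grid <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  roc <- t(vapply(thr_grid, function(t) {
    c(fpr = sum(scores >= t & labels == 0) / max(sum(labels == 0), 1),
      tpr = sum(scores >= t & labels == 1) / max(sum(labels == 1), 1))
  }, numeric(2)))
  structure(list(
    prevalence = mean(labels), accuracy = (tp + tn) / length(labels),
    precision = precision, f1 = f1,
    sensitivity_pct = 100 * sens, specificity_pct = 100 * spec,
    auc = roc_auc(scores, labels),
    auc_ci = auc_confidence_interval(scores, labels),
    threshold = threshold,
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
    roc = roc), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUC %.3f (95%% CI %.3f-%.3f) acc %.3f prec %.3f F1 %.3f Sn %.1f%% Sp %.1f%% @ thr %.2f\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$accuracy, x$precision, x$f1,
    x$sensitivity_pct, x$specificity_pct, x$threshold))
  invisible(x)
}

#' Clinical/graph probability-ensemble weight scan
#'
#' Evaluates `p_ens = (1 - w) p_clinical + w p_graph` on a grid of
#' `grid_size` evenly spaced weights spanning `[0, 1]` inclusive
#' (w = 0 reproduces the clinical model, w = 1 the graph model) and
#' returns the weight maximizing AUC (ties: smaller w).
#'
#' @param clinical_probs,graph_probs aligned probability vectors.
#' @param labels binary labels.
#' @param grid_size number of weights (default 100).
#' @return list with `best_weight`, `best_auc`, and the full `scan`
#'   data.frame (`weight`, `auc`).
#' @export
ensemble_scan <- function(clinical_probs, graph_probs, labels,
                          grid_size = 100L) {
  if (length(clinical_probs) != length(graph_probs) ||
      length(clinical_probs) != length(labels)) {
    stop("probability vectors and labels must be aligned", call. = FALSE)
  }
  weights <- seq(0, 1, length.out = grid_size)
  aucs <- vapply(weights, function(w) {
    roc_auc((1 - w) * clinical_probs + w * graph_probs, labels)
  }, numeric(1))
  best <- which.max(aucs) # which.max takes the first (smallest w) on ties
  list(best_weight = weights[best], best_auc = aucs[best],
       scan = data.frame(weight = weights, auc = aucs))
}

#' Ensemble of a clinical and a graph model bundle
#'
#' @param clinical_bundle,graph_bundle fitted [train_model()] bundles.
#' @param weight ensemble weight in `[0, 1]` (0 = clinical only,
#'   1 = graph only), typically chosen by [ensemble_scan()] on training
#'   probabilities and frozen before touching the test set.
#' @return object of class `ensemble_model` with a `predict` method
#'   taking `list(clinical = ..., graph = ...)` new data.
#' @export
ensemble_model <- function(clinical_bundle, graph_bundle, weight) {
  stopifnot(weight >= 0, weight <= 1)
  structure(list(clinical = clinical_bundle, graph = graph_bundle,
                 weight = weight), class = "ensemble_model")
}

#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  pc <- predict(object$clinical, newdata$clinical)
  pg <- predict(object$graph, newdata$graph)
  (1 - object$weight) * pc + object$weight * pg
}
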