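# Shared helpers over weighted evaluation samples ---------------------------

check_two_classes <- function(sample, what) {
  if (length(unique(sample$y_true)) < 2) {
    abort(paste0(what, " is undefined on a single-class sample (",
                 attr(sample, "strategy")$strategy %||% "unknown strategy", ")."),
          class = "sepsieval_metric_error")
  }
}

sample_prevalence <- function(sample) {
  sum(sample$weight * sample$y_true) / sum(sample$weight)
}

metric_row <- function(sample, name, value, threshold = NA_real_) {
  tibble::tibble(
    name = name, value = value, threshold = threshold,
    prevalence = sample_prevalence(sample),
    n_records = nrow(sample),
    n_stays = attr(sample, "n_stays") %||% length(unique(sample$stay_id))
  )
}

# Weighted operating points of the alarm rule `score > threshold`,
# thresholds descending through the unique scores (and -Inf), cumulative
# weighted TP/FP. Shared by the PR-curve, lifted and utility metrics.
operating_points <- function(sample) {
  ord <- order(sample$y_pred, decreasing = TRUE)
  s <- sample$y_pred[ord]
  wp <- sample$weight[ord] * (sample$y_true[ord] == 1)
  wn <- sample$weight[ord] * (sample$y_true[ord] == 0)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(rowsum(wp, grp, reorder = FALSE)[, 1])
  fp <- cumsum(rowsum(wn, grp, reorder = FALSE)[, 1])
  tibble::tibble(
    score = unique(s), # predicted positive iff y_pred >= score
    tp = tp, fp = fp,
    recall = tp / max(tp[length(tp)], .Machine$double.xmin),
    precision = tp / pmax(tp + fp, .Machine$double.xmin)
  )
}

#' Weighted area under the ROC curve
#'
#' The probability that a randomly chosen positive record outranks a
#' randomly chosen negative one, with record weights and ties credited 0.5.
#' Equals the weighted rank-sum (Wilcoxon) formulation; unaffected by
#' prevalence.
#'
#' @param sample An evaluation-sample tibble with `y_pred`, `y_true`,
#'   `weight` (see [build_evaluation_sample()]).
#' @return A one-row metric tibble `name`, `value`, `threshold`,
#'   `prevalence`, `n_records`, `n_stays`.
#' @export
weighted_auroc <- function(sample) {
  check_two_classes(sample, "AUROC")
  metric_row(sample, "auroc",
             wauroc(sample$y_pred, sample$y_true, sample$weight))
}

# Sort-based weighted AUROC, O(n log n).
wauroc <- function(s, y, w) {
  ord <- order(s)
  s <- s[ord]; y <- y[ord]; w <- w[ord]
  wp <- w * (y == 1)
  wn <- w * (y == 0)
  grp <- cumsum(!duplicated(s))
  wp_g <- rowsum(wp, grp, reorder = FALSE)[, 1]
  wn_g <- rowsum(wn, grp, reorder = FALSE)[, 1]
  below <- cumsum(wn_g) - wn_g
  sum(wp_g * (below + 0.5 * wn_g)) / (sum(wp) * sum(wn))
}

#' Precision-recall curve metrics at a threshold
#'
#' Weighted confusion counts use the alarm rule `score > threshold`
#' consistently across all metrics. AUPRC integrates the step-wise weighted
#' precision-recall curve (no interpolation); linear interpolation between
#' adjacent operating points is used only for the precision-at-recall query,
#' where the target recall need not be attainable exactly.
#'
#' @param sample An evaluation-sample tibble.
#' @param threshold Decision threshold for PPV/NPV/recall.
#' @param recall_target Optional recall at which to interpolate precision.
#' @return A metric tibble with rows `auprc`, `ppv`, `npv`, `recall`, and
#'   `precision_at_recall` when requested.
#' @export
pr_curve_metrics <- function(sample, threshold = 0.5, recall_target = NULL) {
  check_two_classes(sample, "PR metrics")
  op <- operating_points(sample)
  auprc <- sum(diff(c(0, op$recall)) * op$precision)

  pos <- sample$y_true == 1
  alarm <- sample$y_pred > threshold
  tp <- sum(sample$weight[pos & alarm])
  fp <- sum(sample$weight[!pos & alarm])
  fn <- sum(sample$weight[pos & !alarm])
  tn <- sum(sample$weight[!pos & !alarm])
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  recall <- tp / (tp + fn)

  out <- dplyr::bind_rows(
    metric_row(sample, "auprc", auprc),
    metric_row(sample, "ppv", ppv, threshold),
    metric_row(sample, "npv", npv, threshold),
    metric_row(sample, "recall", recall, threshold)
  )
  if (!is.null(recall_target)) {
    out <- dplyr::bind_rows(
      out, metric_row(sample, "precision_at_recall",
                      precision_at_recall(op, recall_target), recall_target))
  }
  out
}

# Linear interpolation of precision between the adjacent operating points
# bracketing the target recall.
precision_at_recall <- function(op, target) {
  if (target <= op$recall[1]) return(op$precision[1])
  approx(op$recall, op$precision, xout = target, ties = "ordered")$y
}

#' Prevalence-normalized ("lifted") metrics
#'
#' PPV and AUPRC divided by the sample prevalence -- an uninformative model
#' scores ~1 on both -- plus the recall at the operating point where
#' precision reaches twice the prevalence. Because the precision-doubling
#' threshold need not exist exactly, `recall_at_2prev` is the maximum recall
#' over achievable operating points with precision >= 2 x prevalence; when
#' no such point exists it is 0 with `flag = "unreached"`.
#'
#' @param sample An evaluation-sample tibble.
#' @param threshold Decision threshold for the underlying PPV.
#' @return A metric tibble with rows `lifted_ppv`, `lifted_auprc`,
#'   `recall_at_2prev` (the latter with a `flag` column).
#' @export
lifted_metrics <- function(sample, threshold = 0.5) {
  check_two_classes(sample, "lifted metrics")
  prev <- sample_prevalence(sample)
  if (prev <= 0) {
    abort("lifted metrics are undefined at zero prevalence.",
          class = "sepsieval_metric_error")
  }
  base <- pr_curve_metrics(sample, threshold = threshold)
  ppv <- base$value[base$name == "ppv"]
  auprc <- base$value[base$name == "auprc"]
  op <- operating_points(sample)
  ok <- op$precision >= 2 * prev
  r2p <- if (any(ok)) max(op$recall[ok]) else 0
  out <- dplyr::bind_rows(
    metric_row(sample, "lifted_ppv", ppv / prev, threshold),
    metric_row(sample, "lifted_auprc", auprc / prev),
    metric_row(sample, "recall_at_2prev", r2p)
  )
  out$flag <- c(NA_character_, NA_character_,
                if (any(ok)) NA_character_ else "unreached")
  out
}

#' Weighted Brier score
#'
#' Weighted mean squared difference between the predicted probability and
#' the binary outcome; 0 for perfect hard predictions, 0.25 for a constant
#' 0.5.
#'
#' @param sample An evaluation-sample tibble with probabilistic scores.
#' @return A one-row metric tibble.
#' @export
brier_score <- function(sample) {
  if (any(sample$y_pred < 0 | sample$y_pred > 1)) {
    abort("Brier score needs scores in [0, 1].", class = "sepsieval_metric_error")
  }
  metric_row(sample, "brier",
             sum(sample$weight * (sample$y_pred - sample$y_true)^2) /
               sum(sample$weight))
}

#' Threshold achieving a target sensitivity
#'
#' Returns the largest decision threshold whose weighted recall (under the
#' alarm rule `score > threshold`) reaches the target. Since recall jumps at
#' positive scores, the supremum is an open bound; the returned value is the
#' critical positive score minus a machine tolerance, so that alarms at the
#' critical score fire.
#'
#' @param sample An evaluation-sample tibble.
#' @param target Target sensitivity in \[0, 1\].
#' @param tol Tolerance subtracted from the critical score.
#' @return A single threshold value.
#' @export
threshold_at_sensitivity <- function(sample, target = 0.80, tol = 1e-8) {
  pos <- sample$y_true == 1
  if (!any(pos)) {
    abort("no positive records; sensitivity target is undefined.",
          class = "sepsieval_metric_error")
  }
  if (target <= 0) return(max(sample$y_pred))
  s <- sample$y_pred[pos]
  w <- sample$weight[pos]
  ord <- order(s, decreasing = TRUE)
  cum <- cumsum(w[ord]) / sum(w)
  k <- which(cum >= target - 1e-12)[1]
  if (is.na(k)) {
    abort("sensitivity target unreachable.", class = "sepsieval_metric_error")
  }
  s[ord][k] - tol
}
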