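# Weighted pool-adjacent-violators: isotonic fit of y on sorted x with
# case weights. Returns the fitted value per input position. Written
# in-package because stats::isoreg does not take weights, and the
# continuous-evaluation samples carry inverse-frequency weights.
pava <- function(y, w) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  # blocks as stacks: value (weighted mean), weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wsum
      wt[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

# Fit a monotone calibration map on (score, label, weight) training records;
# returns a function mapping new scores to calibrated probabilities by
# linear interpolation between fitted points (flat extrapolation).
fit_isotonic_map <- function(score, y, w) {
  ord <- order(score)
  s <- score[ord]; yy <- y[ord]; ww <- w[ord]
  # collapse duplicate scores to their weighted mean label first
  grp <- cumsum(!duplicated(s))
  su <- s[!duplicated(s)]
  wg <- rowsum(ww, grp, reorder = FALSE)[, 1]
  yg <- rowsum(ww * yy, grp, reorder = FALSE)[, 1] / wg
  fit <- pava(yg, wg)
  if (length(su) == 1) {
    v <- fit[1]
    return(function(x) rep(v, length(x)))
  }
  function(x) approx(su, fit, xout = x, rule = 2, ties = "ordered")$y
}

#' Cross-validated isotonic calibration of an evaluation sample
#'
#' Estimates calibrated probabilities without information leakage: stays are
#' split into `folds` folds; within each fold an isotonic (monotone
#' non-decreasing) regression of the outcome on the score is fitted on the
#' training 80% using the record weights, and applied to the held-out 20%.
#' The pooled held-out records form the calibrated sample. Because the map
#' is monotone, within-fold ranking -- and hence discrimination -- is
#' preserved up to ties.
#'
#' @param sample An evaluation-sample tibble.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the stay-level fold split.
#' @return The sample with `y_pred` replaced by the cross-validated
#'   calibrated probability and the raw score retained in `y_raw`; fold
#'   assignments in `fold`.
#' @export
calibrate_isotonic_cv <- function(sample, folds = 5, seed = 1L) {
  stays <- unique(sample$stay_id)
  if (length(stays) < 2 * folds) {
    abort("need at least 2 stays per fold for calibration.",
          class = "sepsieval_contract_error")
  }
  set.seed(seed)
  fold_of <- setNames(sample(rep_len(seq_len(folds), length(stays))), stays)
  rf <- fold_of[sample$stay_id]
  out <- sample
  out$y_raw <- sample$y_pred
  out$fold <- as.integer(rf)
  for (k in seq_len(folds)) {
    test <- rf == k
    y_tr <- sample$y_true[!test]
    if (length(unique(y_tr)) < 2) {
      abort(paste0("calibration fold ", k,
                   " contains a single class; try another seed or a larger sample."),
            class = "sepsieval_contract_error")
    }
    map <- fit_isotonic_map(sample$y_pred[!test], y_tr, sample$weight[!test])
    out$y_pred[test] <- map(sample$y_pred[test])
  }
  out
}
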