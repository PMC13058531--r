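# Shared fixture builders and independent oracles.

# Hand-assembled trajectory table (scores per bin; cases end at onset bin).
make_traj <- function(scores, is_sepsis, onset_bin = NA) {
  n <- length(scores)
  tibble::tibble(
    stay_id = sprintf("s%02d", seq_len(n)),
    is_sepsis = is_sepsis,
    onset_bin = as.integer(onset_bin),
    last_bin = lengths(scores) - 1L,
    scores = scores
  )
}

# Random weighted evaluation sample for metric oracles.
random_sample <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    stay_id = sprintf("s%03d", seq_len(n)),
    bin = NA_integer_,
    y_pred = round(runif(n), 2), # rounding forces ties
    y_true = rbinom(n, 1, 0.4),
    weight = runif(n, 0.2, 2)
  )
}

# Brute-force pairwise AUROC oracle: double loop over (positive, negative)
# record pairs, ties credited half.
auroc_pairwise_oracle <- function(sample) {
  pos <- sample[sample$y_true == 1, ]
  neg <- sample[sample$y_true == 0, ]
  num <- 0
  den <- 0
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(neg))) {
      w <- pos$weight[i] * neg$weight[j]
      num <- num + w * (if (pos$y_pred[i] > neg$y_pred[j]) 1
                        else if (pos$y_pred[i] == neg$y_pred[j]) 0.5 else 0)
      den <- den + w
    }
  }
  num / den
}

# Brute-force onset scan: every (window, SOFA point) combination; reference
# is the minimum SOFA over strictly earlier points inside the same window.
onset_bruteforce_oracle <- function(windows, sofa, delta_min = 2) {
  hits <- c()
  for (k in seq_len(nrow(windows))) {
    for (i in seq_len(nrow(sofa))) {
      t <- sofa$time_h[i]
      if (t < windows$window_start[k] || t > windows$window_end[k]) next
      earlier <- sofa$time_h < t &
        sofa$time_h >= windows$window_start[k] &
        sofa$time_h <= windows$window_end[k]
      if (!any(earlier)) next
      if (sofa$score[i] - min(sofa$score[earlier]) >= delta_min) hits <- c(hits, t)
    }
  }
  if (length(hits) == 0) NA_real_ else min(hits)
}

# Brute-force trailing-window statistic.
roll_oracle <- function(x, w, fun) {
  vapply(seq_along(x), function(t) fun(x[max(1, t - w + 1):t]), numeric(1))
}
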