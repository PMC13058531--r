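#' Bootstrap confidence interval for a sample-level metric
#'
#' Resamples stays (the sampling unit) with replacement, rebuilds the
#' evaluation sample from each resampled trajectory set -- so continuous
#' weights and horizon exclusions are recomputed -- and takes the percentile
#' interval of the metric. Onset matching and prevalence harmonization are
#' frozen in the input trajectories; the bootstrap resamples the observed
#' design, it does not redraw it.
#'
#' @param trajectories Trajectory tibble with onsets assigned.
#' @param builder Function mapping trajectories to an evaluation sample,
#'   e.g. `function(tr) build_continuous(tr, h = 6)`.
#' @param metric Function mapping a sample to a single number; defaults to
#'   the weighted AUROC.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A `sepsis_boot_ci` list: `estimate`, `conf_low`, `conf_high`,
#'   `B`, `n_failed`, `conf`, and the replicate values in `replicates`.
#' @export
bootstrap_ci <- function(trajectories, builder, metric = auroc_value,
                         B = 1000, seed = 1L, conf = 0.95) {
  if (B < 100) abort("use at least 100 bootstrap replicates.",
                     class = "sepsieval_config_error")
  point <- metric(builder(trajectories))
  set.seed(seed)
  n <- nrow(trajectories)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(metric(builder(trajectories[idx, ])),
             sepsieval_metric_error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.05 * B) {
    abort(paste0("metric undefined in ", n_failed, "/", B,
                 " bootstrap replicates; use a larger cohort."),
          class = "sepsieval_contract_error")
  }
  qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 na.rm = TRUE, names = FALSE, type = 7)
  structure(list(estimate = point, conf_low = qs[1], conf_high = qs[2],
                 B = B, n_failed = n_failed, conf = conf, replicates = reps),
            class = "sepsis_boot_ci")
}

#' Convenience metric accessors for bootstrap use
#'
#' @param sample An evaluation-sample tibble.
#' @return A single numeric value.
#' @export
auroc_value <- function(sample) weighted_auroc(sample)$value

#' Paired bootstrap Wald test of an AUROC difference
#'
#' Draws the same bootstrap sample of stays for both evaluation designs,
#' computes the metric for each, and forms the per-replicate difference.
#' The standard error of the difference is the standard deviation of the
#' bootstrap differences; the Wald statistic is the observed difference
#' divided by that SE, with a two-sided p-value from the standard normal
#' distribution. Sharing the resample across designs removes the
#' between-cohort sampling variability from the contrast.
#'
#' @param trajectories Trajectory tibble with onsets assigned.
#' @param builder_a,builder_b Functions mapping trajectories to evaluation
#'   samples (the two designs under contrast).
#' @param metric Metric function; defaults to weighted AUROC.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param center Wald numerator: `"observed"` uses the point-estimate
#'   difference (conventional Wald form); `"boot_mean"` uses the mean of the
#'   bootstrap differences.
#' @return A `sepsis_paired_test` list: `delta_observed`, `se_boot`, `z`,
#'   `p_raw`, `B`, plus replicate vectors `auroc_a`, `auroc_b`.
#' @export
paired_bootstrap_wald <- function(trajectories, builder_a, builder_b,
                                  metric = auroc_value, B = 1000, seed = 1L,
                                  center = c("observed", "boot_mean")) {
  center <- match.arg(center)
  obs_a <- metric(builder_a(trajectories))
  obs_b <- metric(builder_b(trajectories))
  set.seed(seed)
  n <- nrow(trajectories)
  a <- numeric(B); b <- numeric(B)
  for (r in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- trajectories[idx, ]
    a[r] <- tryCatch(metric(builder_a(boot)),
                     sepsieval_metric_error = function(e) NA_real_)
    b[r] <- tryCatch(metric(builder_b(boot)),
                     sepsieval_metric_error = function(e) NA_real_)
  }
  ok <- !is.na(a) & !is.na(b)
  if (sum(!ok) > 0.05 * B) {
    abort(paste0("metric undefined in ", sum(!ok), "/", B,
                 " paired replicates; use a larger cohort."),
          class = "sepsieval_contract_error")
  }
  deltas <- a[ok] - b[ok]
  delta_obs <- obs_a - obs_b
  se <- sd(deltas)
  numerator <- if (center == "observed") delta_obs else mean(deltas)
  if (se == 0) {
    z <- 0
    p <- if (abs(numerator) < .Machine$double.eps^0.5) 1 else 0
  } else {
    z <- numerator / se
    p <- 2 * (1 - pnorm(abs(z)))
  }
  structure(list(delta_observed = delta_obs, se_boot = se, z = z,
                 p_raw = p, B = B, n_used = sum(ok),
                 estimate_a = obs_a, estimate_b = obs_b,
                 auroc_a = a[ok], auroc_b = b[ok], center = center),
            class = "sepsis_paired_test")
}

#' Holm step-down adjustment of a hypothesis family
#'
#' Family-wise error control over a small set of related contrasts (e.g.
#' the three pairwise strategy comparisons, or the single onset-matching
#' contrast per strategy). Wraps `stats::p.adjust(method = "holm")`;
#' adjusted values are returned in the input order.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "sepsieval_contract_error")
  }
  p.adjust(p_values, method = "holm")
}
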