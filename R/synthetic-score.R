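#' Generate a synthetic cohort of hourly risk-score trajectories
#'
#' Simulates the data structure every evaluation strategy consumes: one
#' hourly score trajectory per ICU stay, with a sepsis flag and an onset bin
#' for cases. Case trajectories end at the onset bin (post-onset predictions
#' are never evaluated); control trajectories end at the last data bin before
#' discharge or 7-day truncation, whichever comes first.
#'
#' The latent risk on the logit scale is
#' `baseline + signal_gain * max(0, 1 - (t_onset - t)/signal_lead)` for cases
#' plus stationary AR(1) noise, and `baseline + noise -
#' discharge_recovery * ramp` for controls, where the ramp rises over the
#' final `signal_lead` hours before the last bin. Scores are squashed to
#' (0, 1) with the logistic function; they are correlated with sepsis risk
#' but deliberately not calibrated (calibration is assessed separately).
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per stay and columns `stay_id`, `is_sepsis`,
#'   `onset_bin` (cases: `floor(t_onset)`; controls: `NA` until assigned by
#'   [assign_control_onsets()]), `last_bin`, and a list-column `scores`
#'   holding the per-bin score vector for bins `0..last_bin`.
#' @seealso [generate_ehr_cohort()] for the raw event-stream fidelity level.
#' @examples
#' coh <- generate_score_cohort(cohort_config(n_stays = 50, seed = 1))
#' dplyr::count(coh, is_sepsis)
#' @export
generate_score_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_stays
  is_sepsis <- runif(n) < config$prevalence

  onset_h <- rep(NA_real_, n)
  n_case <- sum(is_sepsis)
  if (n_case > 0) {
    onset_h[is_sepsis] <- draw_truncated(config$onset_time, n_case,
                                         lower = 5, upper = config$max_stay_h,
                                         field = "onset_time")
  }
  los <- rep(NA_real_, n)
  n_ctrl <- sum(!is_sepsis)
  if (n_ctrl > 0) {
    los[!is_sepsis] <- draw_truncated(config$los_control, n_ctrl,
                                      lower = 6, upper = config$max_stay_h,
                                      field = "los_control")
  }

  onset_bin <- ifelse(is_sepsis, floor(onset_h), NA_real_)
  # cases carry bins 0..onset_bin; controls bins 0..floor(los)-1
  last_bin <- ifelse(is_sepsis, onset_bin, pmax(0, floor(los) - 1))

  scores <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- last_bin[i] + 1
    t <- seq_len(nb) - 1
    eta <- config$baseline_logit + ar1_noise(nb, config$noise_rho, config$noise_sd)
    if (is_sepsis[i] && config$signal_gain > 0) {
      eta <- eta + config$signal_gain *
        pmax(0, 1 - (onset_bin[i] - t) / config$signal_lead)
    }
    if (!is_sepsis[i] && config$discharge_recovery > 0) {
      eta <- eta - config$discharge_recovery *
        pmax(0, 1 - (last_bin[i] - t) / config$signal_lead)
    }
    scores[[i]] <- plogis(eta)
  }

  tibble::tibble(
    stay_id = sprintf("stay_%05d", seq_len(n)),
    is_sepsis = is_sepsis,
    onset_bin = as.integer(onset_bin),
    last_bin = as.integer(last_bin),
    scores = scores
  )
}

# Stationary AR(1): x_1 ~ N(0, sd^2); x_t = rho x_{t-1} + sd sqrt(1-rho^2) e_t.
ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  e <- rnorm(n)
  if (rho == 0 || n == 1) return(sd * e)
  x <- numeric(n)
  x[1] <- sd * e[1]
  innov_sd <- sd * sqrt(1 - rho^2)
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov_sd * e[t]
  x
}

# Rejection-sample a duration distribution into [lower, upper].
draw_truncated <- function(spec, n, lower, upper, field) {
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    d <- draw_dist(spec, max(2 * n, 10), field = field)
    out <- c(out, d[d >= lower & d <= upper])
    tries <- tries + 1
    if (tries > 100) {
      abort(paste0("`", field, "` places almost no mass in [", lower, ", ",
                   upper, "] hours; check its parameters."),
            class = "sepsieval_config_error")
    }
  }
  out[seq_len(n)]
}

#' Validate the structural invariants of a trajectory table
#'
#' Checks the contract shared by the generator and every evaluation builder:
#' at least one bin per stay, finite scores in \[0, 1\], score length equal to
#' `last_bin + 1`, and for every stay with an assigned onset,
#' `0 < onset_bin <= last_bin + 1`.
#'
#' @param trajectories A trajectory tibble as returned by
#'   [generate_score_cohort()].
#' @return `trajectories`, invisibly; aborts with an informative message on
#'   the first violated invariant.
#' @export
validate_trajectories <- function(trajectories) {
  need <- c("stay_id", "is_sepsis", "onset_bin", "last_bin", "scores")
  missing <- setdiff(need, names(trajectories))
  if (length(missing) > 0) {
    abort(paste0("trajectory table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "sepsieval_contract_error")
  }
  len <- lengths(trajectories$scores)
  if (any(len < 1)) abort("every trajectory needs at least one bin.",
                          class = "sepsieval_contract_error")
  if (any(len != trajectories$last_bin + 1)) {
    abort("score length must equal last_bin + 1.", class = "sepsieval_contract_error")
  }
  all_s <- unlist(trajectories$scores, use.names = FALSE)
  if (any(!is.finite(all_s)) || any(all_s < 0 | all_s > 1)) {
    abort("scores must be finite and in [0, 1].", class = "sepsieval_contract_error")
  }
  ob <- trajectories$onset_bin
  has <- !is.na(ob)
  if (any(has & (ob <= 0 | ob > trajectories$last_bin + 1))) {
    abort("onset_bin must satisfy 0 < onset_bin <= last_bin + 1.",
          class = "sepsieval_contract_error")
  }
  if (any(trajectories$is_sepsis & is.na(ob))) {
    abort("septic stays must carry an onset_bin.", class = "sepsieval_contract_error")
  }
  invisible(trajectories)
}

#' Cohort prevalence from case and total counts
#'
#' @param n_cases Number of septic stays.
#' @param n_total Total number of stays.
#' @return The prevalence as a fraction in \[0, 1\].
#' @examples
#' cohort_prevalence(4134, 40132) # ~0.103
#' @export
cohort_prevalence <- function(n_cases, n_total) {
  if (n_total <= 0 || n_cases < 0 || n_cases > n_total) {
    abort("need 0 <= n_cases <= n_total with n_total > 0.",
          class = "sepsieval_config_error")
  }
  n_cases / n_total
}
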