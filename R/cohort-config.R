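#' Distribution specifications for cohort simulation
#'
#' Durations in the cohort generator (control length of stay, onset time,
#' post-onset stay) are drawn from parametric distributions described by a
#' small spec object. Log-normal specs are parameterized by their median
#' (hours) because ICU length-of-stay summaries are conventionally reported
#' as medians.
#'
#' @param median Median of the distribution, in hours (log-normal).
#' @param sdlog Standard deviation on the log scale (log-normal).
#' @param shape,rate Gamma parameters.
#' @param min,max Uniform bounds, hours.
#' @param value Constant value, hours.
#' @return A `dist_spec` list with a `family` field and its parameters.
#' @examples
#' dist_lognormal(24, 0.8)
#' @export
dist_lognormal <- function(median, sdlog) {
  if (!is.numeric(median) || median <= 0) {
    abort("`median` must be a positive number of hours.", class = "sepsieval_config_error")
  }
  if (!is.numeric(sdlog) || sdlog <= 0) {
    abort("`sdlog` must be positive.", class = "sepsieval_config_error")
  }
  structure(list(family = "lognormal", meanlog = log(median), sdlog = sdlog),
            class = "dist_spec")
}

#' @rdname dist_lognormal
#' @export
dist_gamma <- function(shape, rate) {
  if (shape <= 0 || rate <= 0) {
    abort("gamma `shape` and `rate` must be positive.", class = "sepsieval_config_error")
  }
  structure(list(family = "gamma", shape = shape, rate = rate), class = "dist_spec")
}

#' @rdname dist_lognormal
#' @export
dist_uniform <- function(min, max) {
  if (min < 0 || max <= min) {
    abort("uniform bounds must satisfy 0 <= min < max.", class = "sepsieval_config_error")
  }
  structure(list(family = "uniform", min = min, max = max), class = "dist_spec")
}

#' @rdname dist_lognormal
#' @export
dist_fixed <- function(value) {
  if (value <= 0) abort("`value` must be positive.", class = "sepsieval_config_error")
  structure(list(family = "fixed", value = value), class = "dist_spec")
}

draw_dist <- function(spec, n, field = "duration") {
  if (!inherits(spec, "dist_spec")) {
    abort(paste0("`", field, "` must be a dist_spec (see dist_lognormal())."),
          class = "sepsieval_config_error")
  }
  switch(spec$family,
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    gamma     = rgamma(n, shape = spec$shape, rate = spec$rate),
    uniform   = runif(n, spec$min, spec$max),
    fixed     = rep(spec$value, n),
    abort(paste0("unknown distribution family in `", field, "`."),
          class = "sepsieval_config_error")
  )
}

dist_median <- function(spec) {
  switch(spec$family,
    lognormal = exp(spec$meanlog),
    gamma     = stats::qgamma(0.5, shape = spec$shape, rate = spec$rate),
    uniform   = (spec$min + spec$max) / 2,
    fixed     = spec$value
  )
}

#' Configure a synthetic ICU cohort
#'
#' Bundles every knob of the synthetic cohort generator: cohort size and
#' sepsis prevalence, length-of-stay and onset-time distributions, the shape
#' of the pre-onset risk signal, the autocorrelated noise of the risk score,
#' and an optional pre-discharge risk decline for controls. The same config
#' plus the same seed reproduces the cohort bit for bit.
#'
#' Defaults emulate the structure of a mixed adult ICU cohort: ~10% sepsis
#' prevalence, log-normal control stays with a 24 h median, log-normal onset
#' times with a 30 h median (sepsis stays run longer than control stays, as
#' observed in large European ICU cohorts), a risk signal ramping up over the
#' final 12 h before onset, and AR(1) score noise.
#'
#' @param n_stays Number of ICU stays.
#' @param prevalence Probability that a stay is septic, strictly in (0, 1).
#' @param los_control Control length-of-stay distribution (hours).
#' @param onset_time Case onset-time distribution (hours since admission);
#'   draws below 5 h are rejected because the eligibility rules exclude
#'   onsets within 4 h of admission.
#' @param post_onset_stay Distribution of additional stay hours after onset;
#'   used only by the raw-EHR generator (score trajectories end at onset).
#' @param signal_lead Hours before onset at which case risk begins rising.
#' @param signal_gain Effect size (logit scale) of the pre-onset ramp.
#' @param noise_rho AR(1) autocorrelation of the score noise, in \[0, 1).
#' @param noise_sd Stationary standard deviation of the score noise.
#' @param discharge_recovery Logit-scale decline of control risk over the
#'   final `signal_lead` hours before the last bin; 0 disables.
#' @param baseline_logit Baseline latent risk on the logit scale.
#' @param abx_confuser_frac Fraction of controls receiving a short (<3 day)
#'   antibiotic course, to exercise labeler specificity.
#' @param sofa_confuser_frac Fraction of controls with a SOFA step of +2
#'   outside any suspicion window.
#' @param outlier_frac Fraction of raw measurements planted outside the
#'   plausibility range of their feature.
#' @param max_stay_h Stay truncation, hours (7 days).
#' @param seed Integer seed.
#' @return A `cohort_config` list, validated.
#' @examples
#' cfg <- cohort_config(n_stays = 200, seed = 1)
#' cfg$prevalence
#' @export
cohort_config <- function(n_stays = 1000,
                          prevalence = 0.103,
                          los_control = dist_lognormal(24, 0.8),
                          onset_time = dist_lognormal(30, 0.6),
                          post_onset_stay = dist_lognormal(48, 0.6),
                          signal_lead = 12,
                          signal_gain = 2,
                          noise_rho = 0.7,
                          noise_sd = 0.5,
                          discharge_recovery = 0,
                          baseline_logit = -2,
                          abx_confuser_frac = 0.30,
                          sofa_confuser_frac = 0.30,
                          outlier_frac = 0.02,
                          max_stay_h = 168,
                          seed = 1L) {
  bad <- function(msg) abort(msg, class = "sepsieval_config_error")
  if (!is.numeric(n_stays) || n_stays < 1) bad("`n_stays` must be a positive count.")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    bad("`prevalence` must lie strictly between 0 and 1.")
  }
  for (f in c("signal_lead", "max_stay_h")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0) bad(paste0("`", f, "` must be a positive number of hours."))
  }
  if (!is.numeric(noise_rho) || noise_rho < 0 || noise_rho >= 1) {
    bad("`noise_rho` must lie in [0, 1).")
  }
  if (noise_sd < 0) bad("`noise_sd` must be non-negative.")
  if (signal_gain < 0) bad("`signal_gain` must be non-negative.")
  if (discharge_recovery < 0) bad("`discharge_recovery` must be non-negative.")
  for (f in c("abx_confuser_frac", "sofa_confuser_frac", "outlier_frac")) {
    v <- get(f)
    if (v < 0 || v > 1) bad(paste0("`", f, "` must lie in [0, 1]."))
  }
  for (f in c("los_control", "onset_time", "post_onset_stay")) {
    spec <- get(f)
    if (!inherits(spec, "dist_spec")) {
      bad(paste0("`", f, "` must be a dist_spec (see dist_lognormal())."))
    }
  }
  structure(list(
    n_stays = as.integer(n_stays), prevalence = prevalence,
    los_control = los_control, onset_time = onset_time,
    post_onset_stay = post_onset_stay,
    signal_lead = signal_lead, signal_gain = signal_gain,
    noise_rho = noise_rho, noise_sd = noise_sd,
    discharge_recovery = discharge_recovery, baseline_logit = baseline_logit,
    abx_confuser_frac = abx_confuser_frac,
    sofa_confuser_frac = sofa_confuser_frac,
    outlier_frac = outlier_frac,
    max_stay_h = max_stay_h, seed = as.integer(seed)
  ), class = "cohort_config")
}
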