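#' Default feature specification for the raw-EHR cohort generator
#'
#' Forty-eight time-varying channels mirroring the layout of routine ICU
#' monitoring data: nine high-frequency vitals/outputs and thirty-nine
#' laboratory parameters sampled at lower, feature-specific rates. Each row
#' carries the emission rate (events per hour), the in-range generating
#' distribution, and the physiological plausibility bounds used by
#' [filter_plausibility()]. Bounds are synthetic stand-ins of realistic
#' magnitude, not a clinical reference.
#'
#' @return A tibble with columns `feature`, `rate_per_h`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
default_feature_spec <- function() {
  vitals <- tibble::tribble(
    ~feature, ~rate_per_h, ~mean, ~sd, ~lower, ~upper,
    "hr",       1.0,  85,  15,  10, 300,
    "sbp",      1.0, 120,  20,  30, 300,
    "dbp",      1.0,  70,  12,  10, 200,
    "map",      1.0,  85,  15,  15, 250,
    "resp",     1.0,  18,   5,   2,  80,
    "temp",     0.5,  37, 0.6,  30,  43,
    "spo2",     1.0,  96,   3,  40, 100,
    "fio2",     0.5,  40,  15,  21, 100,
    "urine",    0.5,  80,  40,   0, 2000
  )
  labs <- tibble::tibble(
    feature = sprintf("lab_%02d", 1:39),
    rate_per_h = rep(c(0.15, 0.08, 0.05), length.out = 39),
    mean = rep(c(100, 10, 1.5), length.out = 39),
    sd = rep(c(20, 3, 0.5), length.out = 39),
    lower = 0,
    upper = rep(c(500, 60, 15), length.out = 39)
  )
  dplyr::bind_rows(vitals, labs)
}

#' Generate a synthetic cohort of raw EHR-like ICU stays
#'
#' Emits irregular time-stamped measurement streams, antibiotic dose events,
#' step-changing SOFA series, and static demographics for each stay --
#' everything the Sepsis-3 labeler and the preprocessing pipeline consume.
#'
#' Planted structure: septic stays receive an antibiotic course (doses every
#' 12 h spanning more than 72 h) whose start lies within 24 h before the
#' planted onset, and a SOFA step of +2 to +4 at the onset time with a
#' non-increasing SOFA before it, so the Sepsis-3 rule recovers the onset
#' exactly. A configurable fraction of controls receive short (< 3 day)
#' antibiotic courses and/or isolated SOFA steps, which must not trigger the
#' labeler. A configurable fraction of measurements is replaced by values
#' strictly outside the feature's plausibility range and flagged, so
#' plausibility-filter recovery can be audited against generator bookkeeping.
#'
#' @param config A [cohort_config()].
#' @param features Feature specification tibble; defaults to
#'   [default_feature_spec()]. Tests may pass a subset for speed.
#' @return A list of class `sepsis_ehr_cohort` with tibbles `stays`
#'   (`stay_id`, `planted_sepsis`, `planted_onset_h`, `age`, `sex`, `height`,
#'   `weight`, `admission_origin`, `los_h`), `measurements` (`stay_id`,
#'   `feature`, `time_h`, `value`, `planted_outlier`), `abx` (`stay_id`,
#'   `drug`, `time_h`) and `sofa` (`stay_id`, `time_h`, `score`).
#' @examples
#' coh <- generate_ehr_cohort(cohort_config(n_stays = 5, seed = 1),
#'                            features = default_feature_spec()[1:3, ])
#' names(coh)
#' @export
generate_ehr_cohort <- function(config, features = default_feature_spec()) {
  stopifnot(inherits(config, "cohort_config"))
  need <- c("feature", "rate_per_h", "mean", "sd", "lower", "upper")
  if (!all(need %in% names(features))) {
    abort("`features` must have columns feature, rate_per_h, mean, sd, lower, upper.",
          class = "sepsieval_config_error")
  }
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_stays
  is_sepsis <- runif(n) < config$prevalence

  onset_h <- rep(NA_real_, n)
  if (any(is_sepsis)) {
    onset_h[is_sepsis] <- draw_truncated(config$onset_time, sum(is_sepsis),
                                         lower = 5, upper = 160, field = "onset_time")
  }
  los <- numeric(n)
  if (any(!is_sepsis)) {
    los[!is_sepsis] <- draw_truncated(config$los_control, sum(!is_sepsis),
                                      lower = 6, upper = 240, field = "los_control")
  }

  stays <- vector("list", n)
  abx <- vector("list", n)
  sofa <- vector("list", n)

  for (i in seq_len(n)) {
    id <- sprintf("stay_%05d", i)
    if (is_sepsis[i]) {
      o <- onset_h[i]
      t_si <- max(0, o - runif(1, 0, 24))
      # course: doses q12h spanning 84 h; the recorded stay must contain it
      doses <- t_si + seq(0, 84, by = 12)
      post <- draw_truncated(config$post_onset_stay, 1, lower = 1, upper = 240,
                             field = "post_onset_stay")
      los_i <- max(o + post, t_si + 88)
      abx[[i]] <- tibble::tibble(stay_id = id, drug = "abx_1", time_h = doses)
      sofa[[i]] <- plant_case_sofa(id, o, los_i)
    } else {
      los_i <- los[i]
      rows <- list()
      has_long <- FALSE
      if (runif(1) < config$abx_confuser_frac) {
        # short course: q12h over 48 h (span < 72 h, never a suspicion)
        start <- runif(1, 0, max(0.1, los_i - 48))
        rows$short <- tibble::tibble(stay_id = id, drug = "abx_1",
                                     time_h = start + seq(0, min(48, los_i - start), by = 12))
      } else if (los_i >= 90 && runif(1) < 0.10) {
        # long course with flat SOFA: suspicion without organ dysfunction
        has_long <- TRUE
        rows$long <- tibble::tibble(stay_id = id, drug = "abx_2",
                                    time_h = seq(2, 2 + 78, by = 12))
      }
      abx[[i]] <- if (length(rows)) dplyr::bind_rows(rows) else NULL
      sofa[[i]] <- plant_control_sofa(id, los_i,
                                      step = !has_long && runif(1) < config$sofa_confuser_frac)
    }
    stays[[i]] <- tibble::tibble(
      stay_id = id,
      planted_sepsis = is_sepsis[i],
      planted_onset_h = if (is_sepsis[i]) onset_h[i] else NA_real_,
      age = round(pmin(95, pmax(18, rnorm(1, 64, 15)))),
      sex = sample(c("male", "female"), 1, prob = c(0.56, 0.44)),
      height = round(rnorm(1, 172, 10)),
      weight = round(rnorm(1, 78, 16)),
      admission_origin = "icu",
      los_h = los_i
    )
  }

  stays <- dplyr::bind_rows(stays)
  measurements <- emit_measurements(stays, features, config$outlier_frac)

  structure(list(
    stays = stays,
    measurements = measurements,
    abx = dplyr::bind_rows(abx),
    sofa = dplyr::bind_rows(sofa)
  ), class = "sepsis_ehr_cohort")
}

# Non-increasing SOFA before onset (so the first qualifying rise is the
# planted one), a +2..+4 step at onset, drift afterwards.
plant_case_sofa <- function(id, onset, los) {
  # a reading 2 h before onset guarantees a within-window reference point
  times_pre <- sort(c(0.5, runif(2, 1, max(1.5, onset - 2.5)), onset - 2))
  base <- sample(2:5, 1)
  pre <- base - cumsum(c(0, runif(length(times_pre) - 1) < 0.3))
  pre <- pmax(pre, 0)
  step <- sample(2:4, 1)
  post_times <- if (los - onset > 2) sort(runif(2, onset + 1, los)) else numeric(0)
  post <- pre[length(pre)] + step + cumsum(sample(c(-1, 0, 1), length(post_times), TRUE))
  tibble::tibble(
    stay_id = id,
    time_h = c(times_pre, onset, post_times),
    score = as.integer(pmax(0, c(pre, pre[length(pre)] + step, post)))
  )
}

# Controls: flat-ish SOFA; optionally one +2 step (harmless without a
# suspicion window).
plant_control_sofa <- function(id, los, step = FALSE) {
  times <- sort(c(0.5, runif(3, 1, max(1.5, los - 0.5))))
  base <- sample(0:3, 1)
  score <- rep(base, length(times))
  if (step && length(times) >= 2) {
    k <- sample(2:length(times), 1)
    score[k:length(score)] <- score[k:length(score)] + 2
  }
  tibble::tibble(stay_id = id, time_h = times, score = as.integer(score))
}

# Vectorized emission over (stay, feature): Poisson-count event times plus a
# guaranteed admission-time vital, values in range, planted outliers strictly
# outside [lower, upper].
emit_measurements <- function(stays, features, outlier_frac) {
  grid <- tidyr::crossing(stays[, c("stay_id", "los_h")], features)
  n_events <- rpois(nrow(grid), grid$rate_per_h * grid$los_h)
  # admission-time reading for every high-frequency channel keeps the data
  # span anchored at t = 0 and avoids artificial leading gaps
  anchored <- grid$rate_per_h >= 0.5
  n_events[anchored] <- pmax(n_events[anchored], 1L)
  idx <- rep(seq_len(nrow(grid)), n_events)
  g <- grid[idx, ]
  first_of_run <- !duplicated(idx)
  time_h <- runif(length(idx), 0, g$los_h)
  time_h[first_of_run & anchored[idx]] <- 0
  value <- pmin(g$upper, pmax(g$lower, rnorm(length(idx), g$mean, g$sd)))
  out <- runif(length(idx)) < outlier_frac
  if (any(out)) {
    hi <- out & runif(length(idx)) < 0.5
    lo <- out & !hi
    value[hi] <- g$upper[hi] + abs(rnorm(sum(hi))) * pmax(g$sd[hi], 1) + 1e-6
    value[lo] <- g$lower[lo] - abs(rnorm(sum(lo))) * pmax(g$sd[lo], 1) - 1e-6
  }
  tibble::tibble(
    stay_id = g$stay_id,
    feature = g$feature,
    time_h = time_h,
    value = value,
    planted_outlier = out
  ) |>
    dplyr::arrange(.data$stay_id, .data$feature, .data$time_h)
}
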