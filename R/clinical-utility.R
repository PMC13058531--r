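#' Decision-curve analysis: net benefit over a threshold grid
#'
#' Net benefit at threshold probability `p_t` is the weighted true-positive
#' fraction minus the weighted false-positive fraction penalized by the
#' threshold odds: `NB = TP/N - (FP/N) * p_t / (1 - p_t)`, with the alarm
#' rule `score > p_t`. Calibrated scores are expected, since `p_t` is
#' interpreted as a probability. Reference policies: treat-none is 0
#' everywhere; treat-all is `prev - (1 - prev) * p_t / (1 - p_t)`.
#'
#' @param sample An evaluation-sample tibble (preferably calibrated; see
#'   [calibrate_isotonic_cv()]).
#' @param thresholds Grid of threshold probabilities in (0, 1).
#' @return A `sepsis_decision_curve` tibble: `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(sample, thresholds = seq(0.01, 0.50, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("decision-curve thresholds must lie strictly in (0, 1).",
          class = "sepsieval_config_error")
  }
  n <- sum(sample$weight)
  prev <- sample_prevalence(sample)
  pos <- sample$y_true == 1
  nb <- vapply(thresholds, function(pt) {
    alarm <- sample$y_pred > pt
    tp <- sum(sample$weight[pos & alarm])
    fp <- sum(sample$weight[!pos & alarm])
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  out <- tibble::tibble(
    threshold = thresholds,
    net_benefit = nb,
    treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
    treat_none = 0
  )
  structure(out, class = c("sepsis_decision_curve", class(out)),
            prevalence = prev)
}

#' Alarm rates per patient-hour, with and without silencing
#'
#' An alarm fires at every pre-onset bin whose score exceeds the threshold.
#' Rates are total alarms divided by total pre-onset patient-hours, reported
#' separately for septic and control stays. With a silencing window, an
#' unsilenced alarm at bin `t` suppresses alarms at bins `t+1 .. t+silencing`;
#' suppressed alarms do not extend the suppression.
#'
#' @param trajectories Trajectory tibble with onsets assigned for every stay.
#' @param threshold Alarm threshold (alarm when `score > threshold`), e.g.
#'   from [threshold_at_sensitivity()].
#' @param silencing Silencing window, hours (0 disables).
#' @return A tibble with one row per group (`sepsis`, `control`):
#'   `threshold`, `group`, `n_stays`, `patient_hours`, `alarms`, `rate`,
#'   `alarms_silenced`, `rate_silenced`, `silencing_h`.
#' @export
alarm_rates <- function(trajectories, threshold, silencing = 4) {
  check_onsets_assigned(trajectories)
  per_stay <- purrr::pmap(
    list(trajectories$scores, trajectories$onset_bin, trajectories$is_sepsis),
    function(s, ob, sep) {
      if (ob < 1) return(c(hours = 0, raw = 0, kept = 0, sepsis = sep))
      alarm <- s[seq_len(ob)] > threshold
      kept <- silence_alarms(alarm, silencing)
      c(hours = ob, raw = sum(alarm), kept = sum(kept), sepsis = sep)
    }
  )
  m <- do.call(rbind, per_stay)
  summarise_group <- function(rows, label) {
    tibble::tibble(
      threshold = threshold, group = label,
      n_stays = nrow(rows),
      patient_hours = sum(rows[, "hours"]),
      alarms = sum(rows[, "raw"]),
      rate = sum(rows[, "raw"]) / max(sum(rows[, "hours"]), 1),
      alarms_silenced = sum(rows[, "kept"]),
      rate_silenced = sum(rows[, "kept"]) / max(sum(rows[, "hours"]), 1),
      silencing_h = silencing
    )
  }
  dplyr::bind_rows(
    summarise_group(m[m[, "sepsis"] == 1, , drop = FALSE], "sepsis"),
    summarise_group(m[m[, "sepsis"] == 0, , drop = FALSE], "control")
  )
}

# Walk the alarm train: an unsilenced alarm at t suppresses t+1 .. t+k.
silence_alarms <- function(alarm, k) {
  if (k <= 0) return(alarm)
  kept <- logical(length(alarm))
  silenced_until <- -1
  for (t in seq_along(alarm)) {
    if (alarm[t] && t > silenced_until) {
      kept[t] <- TRUE
      silenced_until <- t + k
    }
  }
  kept
}
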