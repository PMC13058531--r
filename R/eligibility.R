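#' Apply cohort eligibility filters and 7-day truncation
#'
#' Screens each stay against the inclusion rules of the analysis cohort:
#' ICU admission origin, adult age, no sepsis onset within 4 h of admission,
#' at least 6 h of time-varying data, and no inter-measurement gap of 12 h
#' or more. Retained stays are truncated at `max_stay` hours; a septic stay
#' whose onset falls beyond the truncation point is relabeled as a control
#' rather than excluded.
#'
#' Gaps are computed over the union of all time-varying measurement times,
#' anchored at admission (t = 0), so a stay whose first measurement arrives
#' 12 h or later after admission is excluded. The data span is the time of
#' the last measurement. An onset at exactly 4.0 h is retained ("within
#' 4 hours" is read as strictly less than 4 h).
#'
#' @param cohort A `sepsis_ehr_cohort` (needs `stays` with `age` and
#'   `admission_origin`, and `measurements` with `time_h`).
#' @param labels Label tibble from [label_sepsis()] covering all stays.
#' @param max_stay Truncation point, hours.
#' @return A list with `included` (character vector of retained stay ids),
#'   `report` (one row per stay: `stay_id`, `included`, `exclusion_reasons`
#'   as a comma-separated string, `truncated_at`), and `labels` (the input
#'   labels with truncation-demoted cases relabeled as controls).
#' @export
apply_eligibility <- function(cohort, labels, max_stay = 168) {
  stays <- cohort$stays
  if (!all(stays$stay_id %in% labels$stay_id)) {
    abort("`labels` must cover every stay in the cohort.",
          class = "sepsieval_contract_error")
  }
  meas <- cohort$measurements
  span <- meas |>
    dplyr::summarise(data_span = max(.data$time_h),
                     max_gap = max(diff(sort(c(0, .data$time_h)))),
                     .by = "stay_id")
  lab <- labels[match(stays$stay_id, labels$stay_id), ]

  # truncation demotes cases with onset beyond max_stay to controls
  demote <- !is.na(lab$t_onset) & lab$t_onset > max_stay
  lab$is_sepsis[demote] <- FALSE
  lab$t_onset[demote] <- NA_real_
  lab$sofa_delta[demote] <- NA_integer_

  df <- stays |>
    dplyr::left_join(span, by = "stay_id") |>
    dplyr::mutate(
      data_span = dplyr::coalesce(.data$data_span, 0),
      max_gap = dplyr::coalesce(.data$max_gap, Inf)
    )
  onset <- lab$t_onset

  reasons <- purrr::pmap(
    list(df$admission_origin, df$age, onset, df$data_span, df$max_gap),
    function(origin, age, t_on, span_i, gap_i) {
      r <- character(0)
      if (!identical(origin, "icu")) r <- c(r, "non_icu_origin")
      if (age < 18) r <- c(r, "age_lt_18")
      if (!is.na(t_on) && t_on < 4) r <- c(r, "onset_lt_4h")
      if (span_i < 6) r <- c(r, "data_lt_6h")
      if (gap_i >= 12) r <- c(r, "gap_ge_12h")
      r
    }
  )
  included <- lengths(reasons) == 0
  report <- tibble::tibble(
    stay_id = stays$stay_id,
    included = included,
    exclusion_reasons = purrr::map_chr(reasons, paste, collapse = ","),
    truncated_at = ifelse(included & df$data_span > max_stay, max_stay, NA_real_)
  )
  list(included = stays$stay_id[included], report = report, labels = lab)
}
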