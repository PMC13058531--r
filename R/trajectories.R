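#' Assemble evaluation trajectories from per-bin scores and stay labels
#'
#' Joins a long per-bin score table (from any scorer, e.g.
#' [fit_baseline_scorer()] or an external model) with stay-level sepsis
#' labels into the trajectory table the evaluation strategies consume. Case
#' trajectories are truncated at the onset bin (`floor(t_onset)`) and carry
#' `onset_bin`; control trajectories run to their last scored bin and leave
#' `onset_bin` unset until [assign_control_onsets()]. Stays whose scores do
#' not reach the onset bin, or cases with onset before bin 1, are dropped
#' with a message.
#'
#' @param scores Tibble `stay_id`, `bin`, `score` (contiguous bins from 0).
#' @param labels Tibble `stay_id`, `is_sepsis`, and `t_onset` (hours) or
#'   `onset_bin` for cases.
#' @param max_bin Truncation bin (7 days).
#' @return A trajectory tibble (see [generate_score_cohort()]).
#' @export
trajectories_from_scores <- function(scores, labels, max_bin = 167) {
  lab <- labels
  if (!"onset_bin" %in% names(lab)) {
    lab$onset_bin <- as.integer(floor(lab$t_onset))
  }
  nested <- scores |>
    dplyr::filter(.data$bin <= max_bin) |>
    dplyr::arrange(.data$stay_id, .data$bin) |>
    dplyr::summarise(scores = list(.data$score), n_bins = dplyr::n(),
                     .by = "stay_id")
  tr <- lab |>
    dplyr::inner_join(nested, by = "stay_id") |>
    dplyr::mutate(onset_bin = ifelse(.data$is_sepsis, .data$onset_bin, NA_integer_))
  # truncate cases at the onset bin; drop cases the scores never reach
  ok <- !tr$is_sepsis | (!is.na(tr$onset_bin) & tr$onset_bin >= 1 &
                           tr$onset_bin <= tr$n_bins - 1)
  if (any(!ok)) {
    message(sum(!ok), " case stay(s) dropped: onset bin outside the scored range.")
    tr <- tr[ok, ]
  }
  tr$scores <- purrr::pmap(list(tr$scores, tr$onset_bin, tr$is_sepsis),
                           function(s, ob, sep) if (sep) s[seq_len(ob + 1)] else s)
  out <- tibble::tibble(
    stay_id = tr$stay_id,
    is_sepsis = tr$is_sepsis,
    onset_bin = as.integer(tr$onset_bin),
    last_bin = lengths(tr$scores) - 1L,
    scores = tr$scores
  )
  validate_trajectories(out)
  out
}
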