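# CSV dialects ---------------------------------------------------------------
# Score cohorts travel as two files: a long scores table (stay_id, bin,
# score) and a stay-level table (stay_id, is_sepsis, onset_bin, last_bin).
# Raw EHR cohorts travel as one long event table (stay_id, kind, name,
# time_h, value) with kind in {measurement, abx, sofa, static} plus the
# stay-level statics encoded as static rows.

#' Write and read score cohorts as CSV
#'
#' @param trajectories Trajectory tibble.
#' @param scores_path,stays_path File paths for the per-bin scores and the
#'   stay-level table.
#' @return `write_score_cohort()` returns the paths invisibly;
#'   `read_score_cohort()` returns a trajectory tibble.
#' @export
write_score_cohort <- function(trajectories, scores_path, stays_path) {
  validate_trajectories(trajectories)
  scores <- tibble::tibble(
    stay_id = rep(trajectories$stay_id, lengths(trajectories$scores)),
    bin = unlist(lapply(lengths(trajectories$scores), function(n) seq_len(n) - 1L)),
    score = unlist(trajectories$scores, use.names = FALSE)
  )
  readr::write_csv(scores, scores_path)
  readr::write_csv(
    trajectories[, c("stay_id", "is_sepsis", "onset_bin", "last_bin")],
    stays_path
  )
  invisible(c(scores_path, stays_path))
}

#' @rdname write_score_cohort
#' @export
read_score_cohort <- function(scores_path, stays_path) {
  scores <- readr::read_csv(scores_path, show_col_types = FALSE)
  stays <- readr::read_csv(stays_path, show_col_types = FALSE)
  for (col in c("stay_id", "bin", "score")) {
    if (!col %in% names(scores)) {
      abort(paste0("scores file lacks column `", col, "`."),
            class = "sepsieval_parse_error")
    }
  }
  nested <- scores |>
    dplyr::arrange(.data$stay_id, .data$bin) |>
    dplyr::summarise(scores = list(.data$score), .by = "stay_id")
  out <- stays |>
    dplyr::mutate(is_sepsis = as.logical(.data$is_sepsis),
                  onset_bin = as.integer(.data$onset_bin),
                  last_bin = as.integer(.data$last_bin)) |>
    dplyr::inner_join(nested, by = "stay_id")
  if (nrow(out) != nrow(stays)) {
    abort("stay ids in the scores and stays files do not reconcile.",
          class = "sepsieval_parse_error")
  }
  validate_trajectories(out)
  out
}

#' Write and read raw EHR cohorts as a long event CSV
#'
#' @param cohort A `sepsis_ehr_cohort` (see [generate_ehr_cohort()]).
#' @param path CSV path for the long event table.
#' @return `write_ehr_cohort()` returns the path invisibly;
#'   `read_ehr_cohort()` returns a `sepsis_ehr_cohort` list (without
#'   generator bookkeeping columns).
#' @export
write_ehr_cohort <- function(cohort, path) {
  long <- dplyr::bind_rows(
    cohort$measurements |>
      dplyr::transmute(.data$stay_id, kind = "measurement", name = .data$feature,
                       .data$time_h, .data$value),
    cohort$abx |>
      dplyr::transmute(.data$stay_id, kind = "abx", name = .data$drug,
                       .data$time_h, value = 1),
    cohort$sofa |>
      dplyr::transmute(.data$stay_id, kind = "sofa", name = "sofa",
                       .data$time_h, value = as.numeric(.data$score)),
    cohort$stays |>
      tidyr::pivot_longer(c("age", "height", "weight"), names_to = "name",
                          values_to = "value") |>
      dplyr::transmute(.data$stay_id, kind = "static", .data$name,
                       time_h = 0, .data$value),
    cohort$stays |>
      dplyr::transmute(.data$stay_id, kind = "static", name = "sex",
                       time_h = 0, value = as.numeric(.data$sex == "female"))
  )
  readr::write_csv(dplyr::arrange(long, .data$stay_id, .data$kind, .data$time_h), path)
  invisible(path)
}

#' @rdname write_ehr_cohort
#' @export
read_ehr_cohort <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("stay_id", "kind", "name", "time_h", "value")
  if (!all(need %in% names(long))) {
    abort(paste0("event file must have columns ", paste(need, collapse = ", "), "."),
          class = "sepsieval_parse_error")
  }
  meas <- long |>
    dplyr::filter(.data$kind == "measurement") |>
    dplyr::transmute(.data$stay_id, feature = .data$name, .data$time_h, .data$value)
  statics <- long |>
    dplyr::filter(.data$kind == "static") |>
    tidyr::pivot_wider(id_cols = "stay_id", names_from = "name",
                       values_from = "value")
  stays <- statics |>
    dplyr::mutate(sex = ifelse(.data$sex == 1, "female", "male"),
                  admission_origin = "icu") |>
    dplyr::left_join(
      meas |> dplyr::summarise(los_h = max(.data$time_h), .by = "stay_id"),
      by = "stay_id")
  structure(list(
    stays = stays,
    measurements = meas,
    abx = long |>
      dplyr::filter(.data$kind == "abx") |>
      dplyr::transmute(.data$stay_id, drug = .data$name, .data$time_h),
    sofa = long |>
      dplyr::filter(.data$kind == "sofa") |>
      dplyr::transmute(.data$stay_id, .data$time_h, score = as.integer(.data$value))
  ), class = "sepsis_ehr_cohort")
}

#' Write sepsis labels and evaluation samples as CSV
#'
#' @param labels Label tibble from [label_sepsis()].
#' @param sample An evaluation-sample tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
write_eval_sample <- function(sample, path) {
  readr::write_csv(
    tibble::as_tibble(sample)[, c("stay_id", "bin", "y_pred", "y_true", "weight")],
    path)
  invisible(path)
}
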