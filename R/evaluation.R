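#' Configure an evaluation strategy
#'
#' @param strategy One of `"fixed_horizon"`, `"peak_score"`, `"continuous"`.
#' @param h Prediction horizon in hours (`NA` for full-stay peak score;
#'   required, >= 1, for the other strategies).
#' @param onset_matching Assign control onsets by matching to case onsets?
#' @param target_prevalence Optional patient-level prevalence to harmonize
#'   to by down-sampling controls before sample construction.
#' @param seed Integer seed; required whenever matching or harmonization is
#'   active.
#' @return A validated `strategy_config` list.
#' @export
strategy_config <- function(strategy = c("fixed_horizon", "peak_score", "continuous"),
                            h = 6, onset_matching = FALSE,
                            target_prevalence = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  if (strategy != "peak_score" || !is.na(h)) {
    if (!is.numeric(h) || is.na(h) || h < 1) {
      abort("`h` must be a horizon of at least 1 hour (NA only for full-stay peak score).",
            class = "sepsieval_config_error")
    }
  }
  if ((onset_matching || !is.null(target_prevalence)) && is.null(seed)) {
    abort("`seed` is required when onset matching or harmonization is active.",
          class = "sepsieval_config_error")
  }
  structure(list(strategy = strategy, h = h, onset_matching = onset_matching,
                 target_prevalence = target_prevalence, seed = seed),
            class = "strategy_config")
}

#' Assign hypothetical onsets to control stays
#'
#' Controls lack the reference point that truncates case trajectories, so
#' every evaluation strategy needs a hypothetical control onset. Without
#' matching, it is the bin after the last available data point (discharge or
#' 7-day truncation, whichever came first), so all observed bins are
#' usable. With matching, each control is paired uniformly at random (with
#' replacement) with a sepsis case whose onset does not exceed the
#' control's available data (`case onset_bin <= control last_bin + 1`) and
#' copies that case's onset bin, aligning the length-of-stay distributions
#' of the two groups. Controls with no eligible case fall back to the
#' unmatched rule and are flagged in `match_fallback`.
#'
#' @param trajectories Trajectory tibble (see [generate_score_cohort()]).
#' @param matching Logical; match control onsets to case onsets?
#' @param seed Integer seed for the pairing draw.
#' @return The trajectories with `onset_bin` set for every control and a
#'   logical `match_fallback` column.
#' @export
assign_control_onsets <- function(trajectories, matching = FALSE, seed = NULL) {
  validate_trajectories(trajectories)
  tr <- trajectories
  ctrl <- !tr$is_sepsis
  tr$match_fallback <- FALSE
  if (!matching) {
    tr$onset_bin[ctrl] <- tr$last_bin[ctrl] + 1L
    return(tr)
  }
  case_onsets <- tr$onset_bin[tr$is_sepsis]
  if (length(case_onsets) == 0) {
    abort("onset matching requires at least one sepsis case.",
          class = "sepsieval_contract_error")
  }
  if (is.null(seed)) {
    abort("onset matching requires a seed.", class = "sepsieval_config_error")
  }
  set.seed(seed)
  for (i in which(ctrl)) {
    eligible <- case_onsets[case_onsets <= tr$last_bin[i] + 1L]
    if (length(eligible) == 0) {
      tr$onset_bin[i] <- tr$last_bin[i] + 1L
      tr$match_fallback[i] <- TRUE
    } else {
      tr$onset_bin[i] <- eligible[sample.int(length(eligible), 1)]
    }
  }
  tr
}

#' Harmonize patient-level prevalence by down-sampling controls
#'
#' Removes controls uniformly at random (seeded, without replacement) so
#' that the case fraction matches `target_prevalence` to within the
#' granularity of one patient. Cases are never removed; a cohort whose
#' prevalence already exceeds the target is an error.
#'
#' @param trajectories Trajectory tibble.
#' @param target_prevalence Target case fraction in (0, 1).
#' @param seed Integer seed.
#' @return The subset of trajectories, original row order preserved.
#' @export
harmonize_prevalence <- function(trajectories, target_prevalence, seed) {
  n_case <- sum(trajectories$is_sepsis)
  n_ctrl <- sum(!trajectories$is_sepsis)
  if (n_case == 0) {
    abort("cannot harmonize a cohort without cases.",
          class = "sepsieval_contract_error")
  }
  current <- n_case / (n_case + n_ctrl)
  if (current > target_prevalence) {
    abort(paste0("cohort prevalence (", signif(current, 3),
                 ") already exceeds the target (", target_prevalence,
                 "); down-sampling cases is out of contract."),
          class = "sepsieval_contract_error")
  }
  keep_ctrl <- round(n_case * (1 - target_prevalence) / target_prevalence)
  if (keep_ctrl >= n_ctrl) return(trajectories)
  set.seed(seed)
  ctrl_idx <- which(!trajectories$is_sepsis)
  kept <- sort(sample(ctrl_idx, keep_ctrl))
  trajectories[sort(c(which(trajectories$is_sepsis), kept)), ]
}

new_eval_sample <- function(records, config, n_stays) {
  structure(records, class = c("sepsis_eval_sample", class(records)),
            strategy = config, n_stays = n_stays)
}

#' Build a fixed-horizon evaluation sample
#'
#' One record per stay: the score produced exactly `h` hours before the
#' (actual or hypothetical) onset, using all data available up to that
#' point, labeled by sepsis status. Stays whose onset bin precedes the
#' horizon are excluded and counted in the `n_excluded` attribute, since no
#' prediction exists that early.
#'
#' @param trajectories Trajectory tibble with onsets assigned for every stay
#'   (see [assign_control_onsets()]).
#' @param h Prediction horizon, hours (>= 1).
#' @return An evaluation-sample tibble `stay_id`, `bin`, `y_pred`, `y_true`,
#'   `weight` (all 1), with attributes `strategy` and `n_excluded`.
#' @export
build_fixed_horizon <- function(trajectories, h = 6) {
  check_onsets_assigned(trajectories)
  if (is.na(h) || h < 1) abort("`h` must be >= 1.", class = "sepsieval_config_error")
  keep <- trajectories$onset_bin - h >= 0
  tr <- trajectories[keep, ]
  bin <- tr$onset_bin - h
  records <- tibble::tibble(
    stay_id = tr$stay_id,
    bin = as.integer(bin),
    y_pred = purrr::map2_dbl(tr$scores, bin, ~ .x[[.y + 1]]),
    y_true = as.integer(tr$is_sepsis),
    weight = 1
  )
  out <- new_eval_sample(records, list(strategy = "fixed_horizon", h = h),
                         n_stays = nrow(tr))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Build a peak-score evaluation sample
#'
#' One record per stay: the maximum score over the pre-onset bins
#' `[0, onset_bin)` (the prediction at the onset bin itself is excluded),
#' labeled by sepsis status. With a horizon, the maximum is restricted to
#' the last `h` pre-onset bins `[onset_bin - h, onset_bin)` and stays with
#' `onset_bin < h` are excluded.
#'
#' @param trajectories Trajectory tibble with onsets assigned.
#' @param h Horizon in hours, or `NA` for the full pre-onset stay.
#' @return An evaluation-sample tibble; see [build_fixed_horizon()].
#' @export
build_peak_score <- function(trajectories, h = NA) {
  check_onsets_assigned(trajectories)
  if (!is.na(h) && h < 1) abort("`h` must be >= 1 or NA.", class = "sepsieval_config_error")
  lo <- if (is.na(h)) rep(0L, nrow(trajectories)) else trajectories$onset_bin - as.integer(h)
  keep <- trajectories$onset_bin >= 1 & lo >= 0
  tr <- trajectories[keep, ]
  lo <- lo[keep]
  records <- tibble::tibble(
    stay_id = tr$stay_id,
    bin = NA_integer_,
    y_pred = purrr::pmap_dbl(list(tr$scores, lo, tr$onset_bin),
                             function(s, a, b) max(s[(a + 1):b])),
    y_true = as.integer(tr$is_sepsis),
    weight = 1
  )
  out <- new_eval_sample(records, list(strategy = "peak_score", h = h),
                         n_stays = nrow(tr))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Build a continuous evaluation sample
#'
#' Every pre-onset bin of every stay becomes a record. For cases, bins
#' within `h` hours of onset (`onset_bin - h <= bin < onset_bin`) are
#' positive and earlier bins negative; control bins are all negative. The
#' prediction at the onset bin itself is excluded. The horizon only labels
#' time points, it does not restrict which stays or bins enter. To balance
#' stays of different lengths, each record carries an inverse-frequency
#' weight `1/n_i`, so every stay contributes total weight 1.
#'
#' @param trajectories Trajectory tibble with onsets assigned.
#' @param h Labeling horizon, hours (>= 1).
#' @return An evaluation-sample tibble; per-stay weights sum to 1.
#' @export
build_continuous <- function(trajectories, h = 6) {
  check_onsets_assigned(trajectories)
  if (is.na(h) || h < 1) abort("`h` must be >= 1.", class = "sepsieval_config_error")
  keep <- trajectories$onset_bin >= 1
  tr <- trajectories[keep, ]
  n_i <- tr$onset_bin # records per stay: bins 0 .. onset_bin - 1
  records <- tibble::tibble(
    stay_id = rep(tr$stay_id, n_i),
    bin = unlist(lapply(n_i, function(n) seq_len(n) - 1L), use.names = FALSE),
    y_pred = unlist(purrr::map2(tr$scores, n_i, ~ .x[seq_len(.y)]), use.names = FALSE),
    is_sepsis = rep(tr$is_sepsis, n_i),
    onset_bin = rep(tr$onset_bin, n_i),
    weight = rep(1 / n_i, n_i)
  )
  records$y_true <- as.integer(records$is_sepsis &
                                 records$bin >= records$onset_bin - h)
  records <- records[, c("stay_id", "bin", "y_pred", "y_true", "weight")]
  out <- new_eval_sample(records, list(strategy = "continuous", h = h),
                         n_stays = nrow(tr))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Build an evaluation sample from a strategy configuration
#'
#' Applies, in order: prevalence harmonization (down-sampling controls),
#' control-onset assignment (matched or unmatched), then the strategy's
#' sample builder. Harmonization and matching happen before horizon
#' filtering and before any bootstrap resampling.
#'
#' @param trajectories Trajectory tibble.
#' @param config A [strategy_config()].
#' @return An evaluation-sample tibble.
#' @export
build_evaluation_sample <- function(trajectories, config) {
  stopifnot(inherits(config, "strategy_config"))
  tr <- prepare_trajectories(trajectories, config)
  build_strategy_sample(tr, config)
}

# Design steps that are frozen before bootstrapping: harmonization and
# onset assignment. Bootstrap replicates resample the output of this.
prepare_trajectories <- function(trajectories, config) {
  tr <- trajectories
  if (!is.null(config$target_prevalence)) {
    tr <- harmonize_prevalence(tr, config$target_prevalence,
                               seed = derive_seed(config$seed, 11L))
  }
  assign_control_onsets(tr, matching = config$onset_matching,
                        seed = if (!is.null(config$seed)) derive_seed(config$seed, 12L))
}

build_strategy_sample <- function(trajectories, config) {
  switch(config$strategy,
    fixed_horizon = build_fixed_horizon(trajectories, config$h),
    peak_score = build_peak_score(trajectories, config$h),
    continuous = build_continuous(trajectories, config$h)
  )
}

check_onsets_assigned <- function(trajectories) {
  validate_trajectories(trajectories)
  if (any(is.na(trajectories$onset_bin))) {
    abort("all stays need an assigned onset_bin; run assign_control_onsets() first.",
          class = "sepsieval_contract_error")
  }
}
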