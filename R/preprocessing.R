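#' Remove physiologically implausible measurements
#'
#' Drops raw measurements whose value falls outside the feature's
#' plausibility range (bounds inclusive: a value exactly at a bound is
#' kept). Removed values are treated as never measured downstream.
#'
#' @param measurements Long tibble with `feature` and `value` columns.
#' @param ranges Tibble with `feature`, `lower`, `upper`.
#' @param exempt Character vector of features deliberately left unbounded.
#' @return The kept measurements. The per-feature removal log is attached as
#'   attribute `"removal_log"` and accessible via [plausibility_log()].
#' @examples
#' m <- tibble::tibble(feature = "hr", value = c(80, 600))
#' r <- tibble::tibble(feature = "hr", lower = 0, upper = 300)
#' filter_plausibility(m, r)
#' @export
filter_plausibility <- function(measurements, ranges, exempt = character()) {
  if (any(ranges$lower >= ranges$upper)) {
    abort("plausibility ranges must satisfy lower < upper.",
          class = "sepsieval_config_error")
  }
  feats <- unique(measurements$feature)
  uncovered <- setdiff(feats, c(ranges$feature, exempt))
  if (length(uncovered) > 0) {
    abort(paste0("no plausibility range for feature(s): ",
                 paste(uncovered, collapse = ", "),
                 ". Add them to `ranges` or list them in `exempt`."),
          class = "sepsieval_config_error")
  }
  joined <- dplyr::left_join(measurements, ranges, by = "feature")
  keep <- is.na(joined$lower) |
    (joined$value >= joined$lower & joined$value <= joined$upper)
  log <- measurements[!keep, , drop = FALSE] |>
    dplyr::count(.data$feature, name = "n_removed")
  kept <- measurements[keep, , drop = FALSE]
  attr(kept, "removal_log") <- log
  kept
}

#' @rdname filter_plausibility
#' @param filtered Output of `filter_plausibility()`.
#' @export
plausibility_log <- function(filtered) {
  attr(filtered, "removal_log") %||%
    tibble::tibble(feature = character(), n_removed = integer())
}

#' Aggregate irregular measurements into hourly bins
#'
#' Bins are 0-based and left-closed: bin `t` covers `[t, t+1)` hours since
#' admission. Each (stay, bin, channel) cell takes the median of the raw
#' values falling into it (even counts: midpoint of the two central values);
#' cells with no measurement are missing with `observed = FALSE`. The output
#' grid is dense and contiguous from bin 0 per stay.
#'
#' @param measurements Long tibble `stay_id`, `feature`, `time_h`, `value`.
#' @param n_bins Optional tibble `stay_id`, `n_bins` fixing the bin count
#'   per stay (e.g. from the stay's length); defaults to the bin of the last
#'   measurement plus one.
#' @return A long hourly tibble `stay_id`, `bin`, `feature`, `value`,
#'   `observed`, dense over stays x bins x features.
#' @export
aggregate_hourly <- function(measurements, n_bins = NULL) {
  if (any(measurements$time_h < 0)) {
    abort("measurement times must be non-negative.",
          class = "sepsieval_contract_error")
  }
  agg <- measurements |>
    dplyr::mutate(bin = as.integer(floor(.data$time_h))) |>
    dplyr::summarise(value = median(.data$value),
                     .by = c("stay_id", "bin", "feature"))
  if (is.null(n_bins)) {
    n_bins <- agg |>
      dplyr::summarise(n_bins = max(.data$bin) + 1L, .by = "stay_id")
  }
  feats <- sort(unique(measurements$feature))
  grid <- n_bins |>
    dplyr::reframe(bin = seq_len(.data$n_bins) - 1L, .by = "stay_id") |>
    tidyr::crossing(feature = feats)
  grid |>
    dplyr::left_join(agg, by = c("stay_id", "bin", "feature")) |>
    dplyr::mutate(observed = !is.na(.data$value)) |>
    dplyr::arrange(.data$stay_id, .data$feature, .data$bin)
}

#' Impute an hourly matrix by forward fill with training-mean fallback
#'
#' Within each stay and channel, missing bins inherit the last observed
#' value; bins before the first observation fall back to the supplied
#' per-channel mean (the training-set mean across all patients in the
#' original analysis). Binary missingness indicators -- 1 when the bin holds
#' at least one raw measurement -- are carried along as the `observed`
#' column, one indicator channel per feature.
#'
#' Imputation is idempotent: imputing an already dense matrix is the
#' identity.
#'
#' @param hourly Output of [aggregate_hourly()].
#' @param fallback_means Tibble `feature`, `mean` covering every channel.
#' @return The dense hourly tibble with no missing `value` and the
#'   `observed` indicator preserved.
#' @export
impute_hourly <- function(hourly, fallback_means) {
  feats <- unique(hourly$feature)
  missing_mean <- setdiff(feats, fallback_means$feature)
  if (length(missing_mean) > 0) {
    abort(paste0("no fallback mean for channel(s): ",
                 paste(missing_mean, collapse = ", ")),
          class = "sepsieval_config_error")
  }
  fb <- setNames(fallback_means$mean, fallback_means$feature)
  hourly |>
    dplyr::arrange(.data$stay_id, .data$feature, .data$bin) |>
    dplyr::group_by(.data$stay_id, .data$feature) |>
    dplyr::mutate(value = forward_fill(.data$value, fb[[dplyr::cur_group()$feature]])) |>
    dplyr::ungroup()
}

forward_fill <- function(x, lead_value) {
  obs <- !is.na(x)
  idx <- cummax(ifelse(obs, seq_along(x), 0L))
  out <- ifelse(idx == 0L, lead_value, x[pmax(idx, 1L)])
  out
}

#' Engineer trailing-window temporal features
#'
#' For every channel, computes the minimum, maximum, mean, median, and
#' population variance over the trailing 4, 8, and 16 hourly bins (window
#' ending at the current bin inclusive, truncated at the stay start, so the
#' statistic at bin t uses exactly `min(w, t + 1)` values). Together with
#' the raw channels and the replicated static channels this yields
#' `c * (1 + 15) + n_statics` feature columns -- 772 for the canonical 48
#' time-varying and 4 static channels.
#'
#' Variance uses the population convention (divide by n), so single-value
#' windows have variance 0.
#'
#' @param hourly_dense Imputed hourly tibble from [impute_hourly()].
#' @param statics Optional tibble `stay_id` plus one column per static
#'   channel, replicated across bins.
#' @param windows Trailing window lengths, bins.
#' @param stats Statistics to compute, a subset of
#'   `c("min", "max", "mean", "median", "var")`.
#' @return A wide tibble keyed by `stay_id`, `bin` with columns
#'   `<feature>`, `<feature>__<stat>_<w>h`, and the statics.
#' @export
engineer_temporal_features <- function(hourly_dense, statics = NULL,
                                       windows = c(4, 8, 16),
                                       stats = c("min", "max", "mean", "median", "var")) {
  if (any(is.na(hourly_dense$value))) {
    abort("temporal features need a dense (imputed) hourly matrix.",
          class = "sepsieval_contract_error")
  }
  stats <- match.arg(stats, several.ok = TRUE,
                     choices = c("min", "max", "mean", "median", "var"))
  long <- hourly_dense |>
    dplyr::arrange(.data$stay_id, .data$feature, .data$bin) |>
    dplyr::group_by(.data$stay_id, .data$feature)
  pieces <- list()
  for (w in windows) {
    for (st in stats) {
      col <- paste0("roll__", st, "_", w, "h")
      pieces[[col]] <- long |>
        dplyr::mutate(!!col := roll_stat(.data$value, w, st)) |>
        dplyr::ungroup() |>
        dplyr::pull(!!col)
    }
  }
  base <- long |> dplyr::ungroup() |>
    dplyr::select("stay_id", "bin", "feature", "value")
  rolled <- dplyr::bind_cols(base, tibble::as_tibble(pieces))
  wide <- rolled |>
    tidyr::pivot_wider(
      names_from = "feature",
      values_from = c("value", names(pieces)),
      names_glue = "{feature}{sub('value', '', sub('roll', '', .value))}"
    )
  if (!is.null(statics)) {
    wide <- dplyr::left_join(wide, statics, by = "stay_id")
  }
  dplyr::arrange(wide, .data$stay_id, .data$bin)
}

roll_stat <- function(x, w, stat) {
  n <- length(x)
  fun <- switch(stat,
    min = min, max = max, mean = mean, median = median,
    var = function(v) mean((v - mean(v))^2)
  )
  vapply(seq_len(n), function(t) fun(x[max(1L, t - w + 1L):t]), numeric(1))
}
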