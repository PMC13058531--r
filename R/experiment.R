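#' Define an experiment grid over strategies, matching, and horizons
#'
#' @param strategies Subset of `c("fixed_horizon", "peak_score",
#'   "continuous")`.
#' @param matching Subset of `c(TRUE, FALSE)` (onset matching on/off).
#' @param horizons Prediction horizons in hours (>= 1).
#' @param metrics Metric ids to report; subset of `c("auroc", "auprc",
#'   "ppv", "npv", "recall", "brier", "lifted_ppv", "lifted_auprc",
#'   "recall_at_2prev")`.
#' @param threshold Decision threshold for threshold-based metrics.
#' @param target_prevalence Optional harmonization target.
#' @param B Bootstrap replicates for confidence intervals and tests.
#' @param seed Master seed; per-component seeds are derived from it.
#' @return An `experiment_grid` list.
#' @export
experiment_grid <- function(strategies = c("fixed_horizon", "peak_score", "continuous"),
                            matching = c(FALSE, TRUE),
                            horizons = 6,
                            metrics = "auroc",
                            threshold = 0.5,
                            target_prevalence = NULL,
                            B = 200, seed = 1L) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (length(horizons) == 0 || any(horizons < 1)) {
    abort("`horizons` must be a non-empty set of horizons >= 1.",
          class = "sepsieval_config_error")
  }
  known <- c("auroc", "auprc", "ppv", "npv", "recall", "brier",
             "lifted_ppv", "lifted_auprc", "recall_at_2prev")
  bad <- setdiff(metrics, known)
  if (length(bad) > 0) {
    abort(paste0("unknown metric id(s): ", paste(bad, collapse = ", ")),
          class = "sepsieval_config_error")
  }
  structure(list(strategies = strategies, matching = matching,
                 horizons = horizons, metrics = metrics,
                 threshold = threshold,
                 target_prevalence = target_prevalence,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "experiment_grid")
}

metric_value <- function(sample, id, threshold) {
  switch(id,
    auroc = weighted_auroc(sample)$value,
    brier = brier_score(sample)$value,
    auprc = ,
    ppv = ,
    npv = ,
    recall = {
      m <- pr_curve_metrics(sample, threshold = threshold)
      m$value[m$name == id]
    },
    lifted_ppv = ,
    lifted_auprc = ,
    recall_at_2prev = {
      m <- lifted_metrics(sample, threshold = threshold)
      m$value[m$name == id]
    }
  )
}

#' Run a full evaluation experiment over a strategy grid
#'
#' For every cell (strategy x matching x horizon), the design is prepared
#' once on the full cohort -- prevalence harmonization, then control-onset
#' assignment, both with seeds derived from the master seed -- and each
#' requested metric is computed with a stay-resampling bootstrap confidence
#' interval. Paired bootstrap Wald contrasts are computed per hypothesis
#' family: the three pairwise strategy contrasts within each (matching,
#' horizon) condition, and the single matched-vs-unmatched contrast within
#' each (strategy, horizon), each family Holm-adjusted.
#'
#' @param trajectories Trajectory tibble (e.g. from
#'   [generate_score_cohort()], or scored real data via
#'   [read_score_cohort()]).
#' @param grid An [experiment_grid()].
#' @param out_dir Optional directory; when given, writes `results.csv`,
#'   `contrasts.csv`, and a `manifest.json` run manifest.
#' @return A `sepsis_experiment` list with tibbles `results` (one row per
#'   strategy x matching x horizon x metric) and `contrasts`, plus the grid.
#' @export
run_experiment <- function(trajectories, grid, out_dir = NULL) {
  stopifnot(inherits(grid, "experiment_grid"))
  validate_trajectories(trajectories)

  cells <- tidyr::crossing(strategy = grid$strategies,
                           matching = grid$matching,
                           horizon = grid$horizons)
  prepared <- list()
  for (m in unique(cells$matching)) {
    cfg <- strategy_config("continuous", h = grid$horizons[1],
                           onset_matching = m,
                           target_prevalence = grid$target_prevalence,
                           seed = grid$seed)
    prepared[[as.character(m)]] <- prepare_trajectories(trajectories, cfg)
  }

  results <- list()
  exclusions <- list()
  for (i in seq_len(nrow(cells))) {
    st <- cells$strategy[i]; mt <- cells$matching[i]; h <- cells$horizon[i]
    tr <- prepared[[as.character(mt)]]
    builder <- function(x) build_strategy_sample(x, list(strategy = st, h = h))
    sample <- builder(tr)
    exclusions[[i]] <- tibble::tibble(strategy = st, matching = mt, horizon = h,
                                      n_included = attr(sample, "n_stays"),
                                      n_excluded = attr(sample, "n_excluded"))
    for (id in grid$metrics) {
      ci <- bootstrap_ci(tr, builder,
                         metric = function(s) metric_value(s, id, grid$threshold),
                         B = grid$B,
                         seed = derive_seed(grid$seed, 100L + i))
      results[[length(results) + 1]] <- tibble::tibble(
        strategy = st, matching = mt, horizon = h, metric = id,
        value = ci$estimate, ci_low = ci$conf_low, ci_high = ci$conf_high,
        n_stays = attr(sample, "n_stays"),
        n_records = nrow(sample),
        prevalence = sample_prevalence(sample), B = grid$B
      )
    }
  }
  results <- dplyr::bind_rows(results)

  contrasts <- run_contrasts(prepared, grid)

  out <- structure(list(results = results,
                        contrasts = contrasts,
                        exclusions = dplyr::bind_rows(exclusions),
                        grid = grid),
                   class = "sepsis_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(out_dir, "results.csv"))
    readr::write_csv(contrasts, file.path(out_dir, "contrasts.csv"))
    manifest <- list(
      seed = grid$seed, B = grid$B,
      strategies = grid$strategies, matching = grid$matching,
      horizons = grid$horizons, metrics = grid$metrics,
      n_stays_input = nrow(trajectories),
      exclusions = dplyr::bind_rows(exclusions)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

run_contrasts <- function(prepared, grid) {
  rows <- list()
  # family 1: pairwise strategy contrasts within each matching x horizon
  if (length(grid$strategies) >= 2) {
    pairs <- utils::combn(grid$strategies, 2, simplify = FALSE)
    for (mt in grid$matching) {
      tr <- prepared[[as.character(mt)]]
      for (h in grid$horizons) {
        fam <- purrr::map(pairs, function(pr) {
          tst <- paired_bootstrap_wald(
            tr,
            function(x) build_strategy_sample(x, list(strategy = pr[1], h = h)),
            function(x) build_strategy_sample(x, list(strategy = pr[2], h = h)),
            B = grid$B,
            seed = derive_seed(grid$seed, 200L + h))
          tibble::tibble(contrast_a = pr[1], contrast_b = pr[2],
                         family = "strategy", matching = mt, horizon = h,
                         delta = tst$delta_observed, se = tst$se_boot,
                         z = tst$z, p_raw = tst$p_raw, B = tst$B)
        }) |> dplyr::bind_rows()
        fam$p_holm <- holm_adjust(fam$p_raw)
        rows[[length(rows) + 1]] <- fam
      }
    }
  }
  # family 2: matched vs unmatched within each strategy x horizon (m = 1)
  if (all(c(TRUE, FALSE) %in% grid$matching)) {
    for (st in grid$strategies) {
      for (h in grid$horizons) {
        # paired over the shared stays of both designs: the unmatched
        # trajectory set (harmonization is identical across arms)
        tr_un <- prepared[["FALSE"]]
        tr_ma <- prepared[["TRUE"]]
        common <- intersect(tr_un$stay_id, tr_ma$stay_id)
        tr_both <- tr_un[match(common, tr_un$stay_id), ]
        onset_ma <- tr_ma$onset_bin[match(common, tr_ma$stay_id)]
        builder_un <- function(x) build_strategy_sample(x, list(strategy = st, h = h))
        builder_ma <- function(x) {
          x$onset_bin <- onset_ma[match(x$stay_id, common)]
          build_strategy_sample(x, list(strategy = st, h = h))
        }
        tst <- paired_bootstrap_wald(tr_both, builder_ma, builder_un,
                                     B = grid$B,
                                     seed = derive_seed(grid$seed, 300L + h))
        rows[[length(rows) + 1]] <- tibble::tibble(
          contrast_a = paste0(st, "_matched"),
          contrast_b = paste0(st, "_unmatched"),
          family = "onset_matching", matching = NA, horizon = h,
          delta = tst$delta_observed, se = tst$se_boot, z = tst$z,
          p_raw = tst$p_raw, B = tst$B, p_holm = holm_adjust(tst$p_raw))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(contrast_a = character(), contrast_b = character(),
                          family = character(), matching = logical(),
                          horizon = numeric(), delta = numeric(),
                          se = numeric(), z = numeric(), p_raw = numeric(),
                          B = integer(), p_holm = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Human-readable summary of experiment results
#'
#' Formats each metric as `point (low-high)` to two decimals, the convention
#' of clinical prediction reporting.
#'
#' @param experiment A `sepsis_experiment` from [run_experiment()], or its
#'   `results` tibble.
#' @return A tibble with a `formatted` column; empty with a warning when no
#'   metrics were requested.
#' @examples
#' # report_summary(run_experiment(coh, experiment_grid(...)))
#' @export
report_summary <- function(experiment) {
  results <- if (inherits(experiment, "sepsis_experiment")) experiment$results else experiment
  if (nrow(results) == 0) {
    warn("no metrics in the results; returning an empty report.")
    return(tibble::tibble())
  }
  results |>
    dplyr::mutate(formatted = sprintf("%.2f (%.2f–%.2f)", .data$value,
                                      .data$ci_low, .data$ci_high)) |>
    dplyr::select("strategy", "matching", "horizon", "metric", "formatted")
}
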