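#' Fit a cross-validated ridge-logistic baseline scorer
#'
#' Trains an L2-penalized logistic regression on the engineered feature
#' table under a 5-fold cross-validation scheme split at the patient level
#' (80% of stays train, 20% test per fold), with class weights inversely
#' proportional to class frequencies in the training split. Scores are
#' emitted only for held-out stays, so every stay receives exactly one
#' out-of-fold score per bin.
#'
#' @param features Wide feature tibble keyed by `stay_id`, `bin` (all other
#'   columns are predictors).
#' @param labels Tibble `stay_id`, `bin`, `y` with binary labels aligned to
#'   `features`.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Ridge penalty passed to glmnet.
#' @return A tibble `stay_id`, `bin`, `score`, `fold` with scores in (0, 1).
#' @export
fit_baseline_scorer <- function(features, labels, folds = 5, seed = 1L,
                                lambda = 0.01) {
  df <- dplyr::inner_join(features, labels, by = c("stay_id", "bin"))
  if (nrow(df) != nrow(features)) {
    abort("`labels` must cover every (stay_id, bin) row of `features`.",
          class = "sepsieval_contract_error")
  }
  pred_cols <- setdiff(names(df), c("stay_id", "bin", "y"))
  x <- as.matrix(df[, pred_cols, drop = FALSE])
  y <- df$y
  stays <- unique(df$stay_id)
  if (length(stays) < 2 * folds) {
    abort("need at least 2 stays per fold; supply a larger cohort.",
          class = "sepsieval_contract_error")
  }
  set.seed(seed)
  fold_of <- setNames(sample(rep_len(seq_len(folds), length(stays))), stays)
  row_fold <- fold_of[df$stay_id]

  out <- vector("list", folds)
  for (k in seq_len(folds)) {
    test <- row_fold == k
    y_tr <- y[!test]
    if (length(unique(y_tr)) < 2 || length(unique(y[test])) < 1) {
      abort(paste0("fold ", k, " contains a single class; use a larger cohort."),
            class = "sepsieval_contract_error")
    }
    p <- mean(y_tr)
    # inverse-frequency class weights: positives ~ 1/p, negatives ~ 1/(1-p)
    w <- ifelse(y_tr == 1, 1 / p, 1 / (1 - p))
    fit <- glmnet::glmnet(x[!test, , drop = FALSE], y_tr, family = "binomial",
                          alpha = 0, lambda = c(10 * lambda, lambda),
                          weights = w, standardize = TRUE)
    sc <- as.numeric(predict(fit, x[test, , drop = FALSE], s = lambda,
                             type = "response"))
    out[[k]] <- tibble::tibble(stay_id = df$stay_id[test], bin = df$bin[test],
                               score = sc, fold = k)
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$stay_id, .data$bin)
}
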