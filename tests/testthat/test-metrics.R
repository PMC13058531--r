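test_that("weighted AUROC matches the pairwise oracle on random samples", {
  worst <- 0
  for (s in 1:100) {
    n <- sample(5:30, 1)
    samp <- random_sample(n, seed = 1000 + s)
    if (length(unique(samp$y_true)) < 2) next
    worst <- max(worst, abs(weighted_auroc(samp)$value -
                              auroc_pairwise_oracle(samp)))
  }
  expect_lt(worst, 1e-12)
})

test_that("AUROC endpoints: perfect separation, all ties, single class", {
  mk <- function(pred, true) tibble::tibble(stay_id = as.character(seq_along(pred)),
                                            bin = NA_integer_, y_pred = pred,
                                            y_true = true, weight = 1)
  expect_equal(weighted_auroc(mk(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)))$value, 1)
  expect_equal(weighted_auroc(mk(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)))$value, 0.5)
  expect_error(weighted_auroc(mk(c(0.1, 0.9), c(1, 1))),
               class = "sepsieval_metric_error")
})

test_that("AUROC is invariant to duplicating negatives at half weight", {
  samp <- random_sample(40, seed = 77)
  neg <- samp[samp$y_true == 0, ]
  neg$weight <- neg$weight / 2
  dup <- dplyr::bind_rows(samp |>
                            dplyr::mutate(weight = ifelse(y_true == 0,
                                                          weight / 2, weight)),
                          neg)
  expect_lt(abs(weighted_auroc(samp)$value - weighted_auroc(dup)$value), 1e-12)
})

test_that("PR metrics: perfect separation, interpolation, null AUPRC", {
  mk <- function(pred, true) tibble::tibble(stay_id = as.character(seq_along(pred)),
                                            bin = NA_integer_, y_pred = pred,
                                            y_true = true, weight = 1)
  perfect <- pr_curve_metrics(mk(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)),
                              threshold = 0.5)
  expect_equal(perfect$value[perfect$name == "ppv"], 1)
  expect_equal(perfect$value[perfect$name == "npv"], 1)
  expect_equal(perfect$value[perfect$name == "recall"], 1)
  # two-point curve: linear interpolation at recall 0.75 -> 0.8
  op <- tibble::tibble(recall = c(0.5, 1.0), precision = c(1.0, 0.6))
  expect_equal(sepsieval:::precision_at_recall(op, 0.75), 0.8)
  # label-independent scores: AUPRC ~ prevalence
  set.seed(5)
  n <- 10000
  null_s <- tibble::tibble(stay_id = as.character(1:n), bin = NA_integer_,
                           y_pred = runif(n), y_true = rbinom(n, 1, 0.2),
                           weight = runif(n, 0.5, 1.5))
  m <- pr_curve_metrics(null_s)
  prev <- sum(null_s$weight * null_s$y_true) / sum(null_s$weight)
  expect_lt(abs(m$value[m$name == "auprc"] - prev), 0.02)
})

test_that("lifted metrics normalize by prevalence", {
  mk <- function(pred, true, w = 1) tibble::tibble(
    stay_id = as.character(seq_along(pred)), bin = NA_integer_,
    y_pred = pred, y_true = true, weight = w)
  # perfect classifier at prevalence 0.1 -> lifted PPV = 10
  pred <- c(rep(0.9, 10), rep(0.1, 90))
  true <- c(rep(1, 10), rep(0, 90))
  lm <- lifted_metrics(mk(pred, true), threshold = 0.5)
  expect_equal(lm$value[lm$name == "lifted_ppv"], 10)
  # random scores: lifted AUPRC ~ 1
  set.seed(6)
  n <- 10000
  null_s <- mk(runif(n), rbinom(n, 1, 0.15))
  lm0 <- lifted_metrics(null_s)
  expect_lt(abs(lm0$value[lm0$name == "lifted_auprc"] - 1), 0.15)
  # classifier never reaching precision 2*prev: recall 0 with flag
  anti <- mk(c(0.1, 0.2, 0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0, 0, 0))
  lma <- lifted_metrics(anti)
  expect_equal(lma$value[lma$name == "recall_at_2prev"], 0)
  expect_equal(lma$flag[lma$name == "recall_at_2prev"], "unreached")
})

test_that("Brier score follows its closed forms", {
  mk <- function(pred, true) tibble::tibble(stay_id = as.character(seq_along(pred)),
                                            bin = NA_integer_, y_pred = pred,
                                            y_true = true, weight = 1)
  expect_equal(brier_score(mk(c(1, 0, 1), c(1, 0, 1)))$value, 0)
  expect_equal(brier_score(mk(rep(0.5, 4), c(1, 0, 1, 0)))$value, 0.25)
  # constant p on prevalence q: p^2 (1-q) + (1-p)^2 q
  p <- 0.3; q <- 0.25
  s <- mk(rep(p, 400), rep(c(1, 0, 0, 0), 100))
  expect_equal(brier_score(s)$value, p^2 * (1 - q) + (1 - p)^2 * q)
})

test_that("threshold_at_sensitivity returns the largest qualifying cut", {
  samp <- tibble::tibble(
    stay_id = as.character(1:6), bin = NA_integer_,
    y_pred = c(0.9, 0.8, 0.7, 0.1, 0.5, 0.3),
    y_true = c(1, 1, 1, 1, 0, 0), weight = 1
  )
  thr <- threshold_at_sensitivity(samp, target = 0.75)
  expect_lt(thr, 0.7)
  expect_gt(thr, 0.7 - 1e-6)
  # recall at the returned threshold reaches the target under score > thr
  rec <- sum(samp$y_pred[samp$y_true == 1] > thr) / 4
  expect_gte(rec, 0.75)
  # target 1: just below the minimum positive score
  thr1 <- threshold_at_sensitivity(samp, target = 1)
  expect_lt(thr1, 0.1)
  expect_gt(thr1, 0.1 - 1e-6)
  # target 0: maximal threshold, no alarms needed
  expect_equal(threshold_at_sensitivity(samp, target = 0), 0.9)
})

test_that("isotonic calibration improves anti-calibrated scores, preserves ranking", {
  set.seed(12)
  n_stays <- 200
  p_true <- runif(n_stays)
  samp <- tibble::tibble(
    stay_id = sprintf("s%03d", 1:n_stays), bin = NA_integer_,
    y_pred = 1 - p_true, # anti-calibrated but monotone-invertible
    y_true = rbinom(n_stays, 1, p_true), weight = 1
  )
  cal <- calibrate_isotonic_cv(samp, folds = 5, seed = 3)
  expect_lt(brier_score(cal)$value, brier_score(samp)$value)
  # already-calibrated scores: Brier essentially unchanged
  set.seed(13)
  n2 <- 10000
  p2 <- runif(n2)
  good <- tibble::tibble(stay_id = sprintf("t%05d", 1:n2), bin = NA_integer_,
                         y_pred = p2, y_true = rbinom(n2, 1, p2), weight = 1)
  cal2 <- calibrate_isotonic_cv(good, folds = 5, seed = 3)
  expect_lt(abs(brier_score(cal2)$value - brier_score(good)$value), 0.005)
  # a monotone map preserves weighted AUROC up to tie granularity; checked
  # within one fold of the well-calibrated sample, where the fitted map is
  # close to the identity and tie blocks are small
  within_fold <- cal2[cal2$fold == 1, ]
  a_raw <- weighted_auroc(dplyr::mutate(within_fold, y_pred = y_raw))$value
  a_cal <- weighted_auroc(within_fold)$value
  expect_lte(abs(a_cal - a_raw), 0.05) # ties can only move toward 0.5
})

test_that("weighted PAVA reproduces stats::isoreg on unweighted data", {
  set.seed(44)
  x <- sort(runif(50))
  y <- x + rnorm(50, sd = 0.3)
  fit_pkg <- sepsieval:::pava(y, rep(1, 50))
  fit_ref <- stats::isoreg(x, y)$yf
  expect_equal(fit_pkg, fit_ref, tolerance = 1e-10)
})

test_that("decision curves follow the net-benefit closed forms", {
  # TP=30, FP=10, N=100 at p_t = 0.5 -> NB = 0.30 - 0.10 = 0.20
  samp <- tibble::tibble(
    stay_id = as.character(1:100), bin = NA_integer_,
    y_pred = c(rep(0.9, 30), rep(0.9, 10), rep(0.1, 60)),
    y_true = c(rep(1, 30), rep(0, 10), rep(0, 55), rep(1, 5)),
    weight = 1
  )
  dc <- decision_curve(samp, thresholds = 0.5)
  expect_equal(dc$net_benefit, 0.30 - 0.10)
  expect_equal(dc$treat_none, 0)
  prev <- mean(samp$y_true)
  expect_equal(dc$treat_all, prev - (1 - prev) * 0.5 / 0.5)
  # sanity: model NB never exceeds prevalence
  dcg <- decision_curve(samp)
  expect_true(all(dcg$net_benefit <= prev + 1e-12))
  expect_error(decision_curve(samp, thresholds = c(0, 0.5)),
               class = "sepsieval_config_error")
})

test_that("alarm rates honor the strict threshold and the silencing walk", {
  # alarms at bins 1,2,3,8 with 4 h silencing -> unsilenced at 1 and 8
  scores <- rep(0.1, 10)
  scores[c(2, 3, 4, 9)] <- 0.9 # bins 1,2,3,8 (0-based)
  tr <- make_traj(list(scores), is_sepsis = TRUE, onset_bin = 10)
  ar <- alarm_rates(tr, threshold = 0.5, silencing = 4)
  sep <- ar[ar$group == "sepsis", ]
  expect_equal(sep$alarms, 4)
  expect_equal(sep$alarms_silenced, 2)
  expect_equal(sep$patient_hours, 10)
  expect_equal(sep$rate, 0.4)
  # silencing 0 leaves rates unchanged
  ar0 <- alarm_rates(tr, threshold = 0.5, silencing = 0)
  expect_equal(ar0$rate_silenced[1], ar0$rate[1])
  # nothing above threshold: all rates zero
  arq <- alarm_rates(tr, threshold = 0.95)
  expect_true(all(arq$rate == 0) && all(arq$rate_silenced == 0))
})

test_that("all metrics reduce to textbook formulas at unit weights", {
  set.seed(91)
  n <- 500
  samp <- tibble::tibble(stay_id = as.character(1:n), bin = NA_integer_,
                         y_pred = runif(n),
                         y_true = rbinom(n, 1, plogis(3 * runif(n) - 1.5)),
                         weight = 1)
  samp$y_true <- as.integer(samp$y_true)
  # unweighted rank formulation
  r <- rank(samp$y_pred)
  n1 <- sum(samp$y_true); n0 <- n - n1
  auc_rank <- (sum(r[samp$y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_equal(weighted_auroc(samp)$value, auc_rank, tolerance = 1e-12)
  expect_equal(brier_score(samp)$value, mean((samp$y_pred - samp$y_true)^2))
})
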