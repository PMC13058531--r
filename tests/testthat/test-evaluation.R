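traj4 <- function() {
  make_traj(
    scores = list(c(0.1, 0.4, 0.2, 0.3), # control, 4 bins
                  c(0.2, 0.3, 0.6, 0.8, 0.9), # case, onset at bin 4
                  c(0.1, 0.2), # short control
                  c(0.3, 0.5, 0.7)), # case, onset at bin 2
    is_sepsis = c(FALSE, TRUE, FALSE, TRUE),
    onset_bin = c(NA, 4, NA, 2)
  )
}

test_that("control onsets: unmatched rule, matching, and fallback", {
  tr <- traj4()
  un <- assign_control_onsets(tr, matching = FALSE)
  expect_equal(un$onset_bin[!un$is_sepsis], un$last_bin[!un$is_sepsis] + 1L)
  # single eligible case: the onset is copied
  ma <- assign_control_onsets(tr, matching = TRUE, seed = 1)
  expect_equal(ma$onset_bin[1], 4L) # control last_bin 3 -> both cases eligible? 4 <= 4
  expect_true(ma$onset_bin[1] %in% c(2L, 4L))
  # short control (last_bin 1): only onset <= 2 eligible
  expect_equal(ma$onset_bin[3], 2L)
  expect_false(any(ma$match_fallback))
  # no eligible case -> fallback to last bin + 1, flagged
  tr2 <- traj4()
  tr2$onset_bin[c(2, 4)] <- c(5L, 5L)
  tr2$last_bin[c(2, 4)] <- c(4L, 4L)
  tr2$scores[[4]] <- c(tr2$scores[[4]], 0.1, 0.1)
  tr2$scores[[2]] <- tr2$scores[[2]]
  ma2 <- assign_control_onsets(tr2, matching = TRUE, seed = 1)
  expect_equal(ma2$onset_bin[3], 2L) # last_bin 1 + 1
  expect_true(ma2$match_fallback[3])
  # matching with no cases errors
  tr3 <- traj4()[c(1, 3), ]
  expect_error(assign_control_onsets(tr3, matching = TRUE, seed = 1),
               class = "sepsieval_contract_error")
})

test_that("matched control onsets reproduce the conditional case-onset law", {
  ok <- 0
  for (s in 1:20) {
    cfg <- cohort_config(n_stays = 1000, prevalence = 0.3, signal_gain = 0,
                         los_control = dist_lognormal(72, 0.4),
                         onset_time = dist_lognormal(16, 0.4), seed = s)
    coh <- generate_score_cohort(cfg)
    ma <- assign_control_onsets(coh, matching = TRUE, seed = s + 300)
    p <- suppressWarnings(stats::wilcox.test(
      ma$onset_bin[!ma$is_sepsis & !ma$match_fallback],
      ma$onset_bin[ma$is_sepsis]))$p.value
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, 18)
})

test_that("fixed-horizon samples take the score exactly h hours before onset", {
  tr <- assign_control_onsets(traj4(), matching = FALSE)
  s <- build_fixed_horizon(tr, h = 2)
  # case with onset_bin 4 -> score at bin 2; control last_bin 3 -> onset 4 -> bin 2
  expect_equal(s$y_pred[s$stay_id == "s02"], 0.6)
  expect_equal(s$y_pred[s$stay_id == "s01"], 0.2)
  expect_equal(s$weight, rep(1, nrow(s)))
  # stays with onset_bin < h are excluded and counted
  s6 <- build_fixed_horizon(tr, h = 3)
  expect_false("s03" %in% s6$stay_id) # onset 2 < 3
  expect_equal(attr(s6, "n_excluded"), 2L) # s03 and s04 (onset 2)
  expect_error(build_fixed_horizon(tr, h = 0), class = "sepsieval_config_error")
})

test_that("peak-score samples maximize over the pre-onset range", {
  tr <- make_traj(list(c(0.1, 0.4, 0.2), c(0.2, 0.5, 0.3, 0.6)),
                  is_sepsis = c(TRUE, FALSE), onset_bin = c(3, NA)) |>
    assign_control_onsets(matching = FALSE)
  s <- build_peak_score(tr)
  expect_equal(s$y_pred[s$stay_id == "s01"], 0.4) # max over bins 0..2
  expect_equal(s$y_pred[s$stay_id == "s02"], 0.6)
  # horizon restricts to the last h pre-onset bins
  s1 <- build_peak_score(tr, h = 1)
  expect_equal(s1$y_pred[s1$stay_id == "s01"], 0.2) # bin 2 only
})

test_that("continuous samples label the horizon and weight stays equally", {
  tr <- make_traj(list(seq(0.1, 1, 0.1)[1:10], c(0.2, 0.3, 0.1, 0.4,
                                                 0.2, 0.3, 0.1, 0.2)),
                  is_sepsis = c(TRUE, FALSE), onset_bin = c(10, NA)) |>
    assign_control_onsets(matching = FALSE)
  s <- build_continuous(tr, h = 6)
  case <- s[s$stay_id == "s01", ]
  expect_equal(nrow(case), 10)
  expect_equal(case$y_true, c(rep(0L, 4), rep(1L, 6)))
  expect_equal(case$weight, rep(0.1, 10))
  ctrl <- s[s$stay_id == "s02", ]
  expect_equal(nrow(ctrl), 8)
  expect_true(all(ctrl$y_true == 0))
  expect_equal(ctrl$weight, rep(1 / 8, 8))
  # total weight equals the number of included stays
  expect_equal(sum(s$weight), 2)
})

test_that("increasing the horizon never flips a positive label to negative", {
  coh <- generate_score_cohort(cohort_config(n_stays = 60, seed = 13))
  tr <- assign_control_onsets(coh, matching = FALSE)
  prev <- NULL
  for (h in c(2, 6, 12, 24)) {
    s <- build_continuous(tr, h = h)
    if (!is.null(prev)) expect_true(all(s$y_true >= prev$y_true))
    prev <- s
  }
})

test_that("prevalence harmonization down-samples controls exactly", {
  coh <- generate_score_cohort(cohort_config(n_stays = 2100, prevalence = 0.05,
                                             seed = 4))
  n_case <- sum(coh$is_sepsis)
  out <- harmonize_prevalence(coh, 0.10, seed = 2)
  expect_equal(sum(out$is_sepsis), n_case) # cases never removed
  expect_equal(sum(!out$is_sepsis), round(n_case * 0.9 / 0.1))
  # seeded: identical retained sets across runs
  expect_identical(out, harmonize_prevalence(coh, 0.10, seed = 2))
  # target below current prevalence is out of contract
  expect_error(harmonize_prevalence(coh, 0.01, seed = 2),
               class = "sepsieval_contract_error")
  # target equal to current prevalence is the identity
  cur <- n_case / nrow(coh)
  expect_identical(harmonize_prevalence(coh, cur + 1e-9, seed = 2), coh)
})

test_that("the three builders consume identical trajectories (panel consistency)", {
  coh <- generate_score_cohort(cohort_config(n_stays = 80, seed = 19))
  tr <- assign_control_onsets(coh, matching = FALSE)
  before <- tr
  s1 <- build_fixed_horizon(tr, 6)
  s2 <- build_peak_score(tr)
  s3 <- build_continuous(tr, 6)
  expect_identical(tr, before) # builders never mutate the cohort
  ids <- tr$stay_id[tr$onset_bin >= 6]
  expect_setequal(s1$stay_id, ids)
  expect_setequal(unique(s3$stay_id), tr$stay_id)
})
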