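test_that("antibiotic course detection follows the gap and span rules", {
  # q24h over exactly 3 days qualifies; suspicion time is the first dose
  one <- find_antibiotic_courses(c(0, 20, 40, 60, 72))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 0)
  # a 30 h gap breaks the run
  expect_equal(nrow(find_antibiotic_courses(c(0, 30))), 0L)
  # span strictly below 72 h does not qualify
  expect_equal(nrow(find_antibiotic_courses(c(0, 24, 48, 71))), 0L)
  # a 28 h gap splits the run; the leading run spans only 72 h
  split <- find_antibiotic_courses(c(0, 24, 48, 72, 100, 130))
  expect_equal(nrow(split), 1L)
  expect_equal(split$start, 0)
  expect_equal(split$end, 72)
  expect_error(find_antibiotic_courses(c(10, 5)),
               class = "sepsieval_contract_error")
})

test_that("adding a dose inside a course never removes it or delays SI", {
  doses <- c(0, 20, 40, 60, 80)
  base <- find_antibiotic_courses(doses)
  for (extra in c(5, 30, 55, 79)) {
    with_extra <- find_antibiotic_courses(sort(c(doses, extra)))
    expect_gte(nrow(with_extra), nrow(base))
    expect_lte(with_extra$start[1], base$start[1])
  }
})

test_that("suspicion windows span exactly -48/+24 around the SI time", {
  w <- suspicion_windows(tibble::tibble(start = c(10, 100), end = c(90, 180),
                                        n_doses = c(5L, 5L)))
  expect_equal(w$window_end - (w$t_si - 48), c(72, 72))
  expect_equal(w$window_start, c(0, 52)) # clipped at admission
})

test_that("onset detection matches the worked examples", {
  w <- tibble::tibble(t_si = 60, window_start = 12, window_end = 84)
  s <- tibble::tibble(time_h = c(40, 70), score = c(2L, 5L))
  res <- detect_onset(w, s)
  expect_true(res$is_sepsis)
  expect_equal(res$t_onset, 70)
  expect_equal(res$sofa_delta, 3L)
  # a rise of exactly 1 never qualifies
  s1 <- tibble::tibble(time_h = c(40, 70), score = c(2L, 3L))
  expect_false(detect_onset(w, s1)$is_sepsis)
  # earliest qualifying onset across two windows wins
  w2 <- tibble::tibble(t_si = c(25, 85), window_start = c(0, 37),
                       window_end = c(49, 109))
  s2 <- tibble::tibble(time_h = c(10, 30, 60, 90), score = c(2L, 4L, 1L, 4L))
  res2 <- detect_onset(w2, s2)
  expect_equal(res2$t_onset, 30)
})

test_that("onset detection agrees with the brute-force scan on random stays", {
  set.seed(42)
  for (i in 1:50) {
    n_w <- sample(1:3, 1)
    t_si <- sort(runif(n_w, 0, 120))
    w <- tibble::tibble(t_si = t_si, window_start = pmax(0, t_si - 48),
                        window_end = t_si + 24)
    n_s <- sample(2:10, 1)
    s <- tibble::tibble(time_h = sort(runif(n_s, 0, 160)),
                        score = sample(0:8, n_s, replace = TRUE))
    mine <- suppressWarnings(detect_onset(w, s))
    oracle <- onset_bruteforce_oracle(w, s)
    if (is.na(oracle)) {
      expect_false(mine$is_sepsis)
    } else {
      expect_true(mine$is_sepsis)
      expect_equal(mine$t_onset, oracle)
    }
  }
})

test_that("empty SOFA with windows present labels non-sepsis with a warning", {
  w <- tibble::tibble(t_si = 10, window_start = 0, window_end = 34)
  expect_warning(res <- detect_onset(w, tibble::tibble(time_h = numeric(),
                                                       score = integer())))
  expect_false(res$is_sepsis)
  expect_true(res$no_sofa)
})

test_that("the labeler recovers planted case-control assignment", {
  cfg <- cohort_config(n_stays = 500, seed = 17)
  coh <- generate_ehr_cohort(cfg, features = default_feature_spec()[1:4, ])
  labs <- label_sepsis(coh)
  truth <- coh$stays$planted_sepsis
  pred <- labs$is_sepsis[match(coh$stays$stay_id, labs$stay_id)]
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
  # recovered onsets equal the planted SOFA-step times
  both <- truth & pred
  expect_equal(labs$t_onset[match(coh$stays$stay_id[both], labs$stay_id)],
               coh$stays$planted_onset_h[both])
})

test_that("eligibility filters exclude and truncate per the cohort rules", {
  mk_cohort <- function(meas_times, age = 50, origin = "icu") {
    list(
      stays = tibble::tibble(stay_id = "s1", age = age,
                             admission_origin = origin, los_h = max(meas_times)),
      measurements = tibble::tibble(stay_id = "s1", feature = "hr",
                                    time_h = meas_times, value = 80)
    )
  }
  lab0 <- tibble::tibble(stay_id = "s1", is_sepsis = FALSE, t_onset = NA_real_,
                         si_time = NA_real_, sofa_delta = NA_integer_)
  # 5 h of data -> excluded
  r <- apply_eligibility(mk_cohort(c(0, 2, 5)), lab0)$report
  expect_equal(r$exclusion_reasons, "data_lt_6h")
  # 20 h gap -> excluded
  r <- apply_eligibility(mk_cohort(c(seq(0, 20), seq(40, 60))), lab0)$report
  expect_equal(r$exclusion_reasons, "gap_ge_12h")
  # onset at 3.5 h -> excluded; at exactly 4.0 h -> retained
  lab35 <- dplyr::mutate(lab0, is_sepsis = TRUE, t_onset = 3.5, sofa_delta = 2L)
  ok <- mk_cohort(seq(0, 24))
  expect_equal(apply_eligibility(ok, lab35)$report$exclusion_reasons, "onset_lt_4h")
  lab40 <- dplyr::mutate(lab35, t_onset = 4.0)
  expect_true(apply_eligibility(ok, lab40)$report$included)
  # age and origin filters, with all reasons logged
  r <- apply_eligibility(mk_cohort(c(0, 2, 5), age = 16, origin = "ward"), lab0)$report
  expect_equal(r$exclusion_reasons, "non_icu_origin,age_lt_18,data_lt_6h")
  # onset beyond 7 days demotes the stay to control
  lab200 <- dplyr::mutate(lab35, t_onset = 200)
  out <- apply_eligibility(mk_cohort(seq(0, 200)), lab200)
  expect_false(out$labels$is_sepsis)
  expect_true(out$report$included)
  expect_equal(out$report$truncated_at, 168)
})
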