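test_that("observer psychometric function has the 3AFC form", {
  obs <- observer_model(alpha = 1, beta = 3, lapse = 0.05)
  expect_equal(observer_p_correct(obs, 0), 1 / 3)
  expect_equal(observer_p_correct(obs, 100), 1 / 3 + (2 / 3 - 0.05),
               tolerance = 1e-9)
  # monotone non-decreasing
  grid <- observer_p_correct(obs, seq(0, 5, by = 0.1))
  expect_true(all(diff(grid) >= 0))
  # algebraic inversion: x solving p = 0.7071
  x <- obs$alpha *
    (-log(1 - (2^(-1 / 2) - 1 / 3) / (2 / 3 - obs$lapse)))^(1 / obs$beta)
  expect_equal(observer_p_correct(obs, x), 2^(-1 / 2), tolerance = 1e-12)
})

test_that("convergence point matches a root-finding oracle and scales with alpha", {
  obs <- observer_model(alpha = 1, beta = 3, lapse = 0)
  cp <- convergence_point(obs)
  root <- stats::uniroot(
    function(x) observer_p_correct(obs, x) - 2^(-1 / 2),
    c(1e-6, 50), tol = 1e-10)$root
  expect_equal(cp, root, tolerance = 1e-6)
  for (k in c(0.2, 0.5, 2, 4)) {
    expect_equal(convergence_point(observer_model(alpha = k, beta = 3)),
                 k * cp, tolerance = 1e-9)
  }
  expect_error(convergence_point(observer_model(alpha = 1, beta = 3,
                                                lapse = 0.3738)),
               "unreachable")
})

test_that("forced observers produce the hand-traceable tracks", {
  # always correct: drop by one step after every second trial
  dn <- run_staircase(NULL, staircase_config(max_trials = 12),
                      responses = TRUE)
  expect_equal(dn$trials$excursion, c(6, 6, 5, 5, 4, 4, 3, 3, 2, 2, 1, 1))
  expect_equal(length(dn$reversal_trials), 0)
  expect_false(dn$complete)

  # always wrong: rise every trial, never reverse
  up <- run_staircase(NULL, staircase_config(max_trials = 10),
                      responses = FALSE)
  expect_equal(up$trials$excursion, 6:15)
  expect_equal(length(up$reversal_trials), 0)
})

test_that("a fixed response sequence replays the 2-down-1-up rule exactly", {
  seqs <- list(rep(c(TRUE, TRUE, FALSE), 60),
               rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 60),
               rep(c(TRUE, FALSE), 90))
  for (resp in seqs) {
    track <- run_staircase(NULL, staircase_config(max_trials = 180),
                           responses = resp)
    oracle <- replay_staircase(resp[seq_len(nrow(track$trials))])
    expect_equal(track$trials$excursion, oracle$excursion,
                 tolerance = 1e-12)
    expect_equal(track$trials$is_reversal, oracle$is_reversal)
  }
})

test_that("every excursion change is plus/minus the scheduled step and floored", {
  set.seed(41)
  cfg <- staircase_config()
  for (i in 1:20) {
    obs <- observer_model(alpha = stats::runif(1, 0.1, 3), beta = 3,
                          lapse = stats::runif(1, 0, 0.05))
    tr <- run_staircase(obs, cfg)
    exc <- tr$trials$excursion
    expect_true(all(exc >= cfg$floor_excursion - 1e-12))
    if (tr$complete)
      expect_equal(length(tr$reversal_trials), cfg$total_reversals)
    changes <- diff(exc)
    # active step at each trial: 1 before the 4th reversal, 0.1 before the
    # 8th, 0.02 afterwards
    nrev_before <- cumsum(c(0, tr$trials$is_reversal))[seq_along(exc)]
    active <- cfg$steps[findInterval(nrev_before, cfg$step_after) + 1]
    for (t in seq_along(changes)) {
      at_floor <- exc[t + 1] == cfg$floor_excursion &&
        changes[t] > -active[t]
      expect_true(abs(abs(changes[t]) - active[t]) < 1e-12 ||
                    changes[t] == 0 || at_floor)
    }
  }
})

test_that("staircase estimates converge to the 70.71%-correct point", {
  set.seed(42)
  for (alpha in c(0.5, 2)) {
    obs <- observer_model(alpha = alpha, beta = 3, lapse = 0.02)
    cp <- convergence_point(obs)
    est <- replicate(200, run_staircase(obs)$threshold_estimate)
    expect_lt(abs(mean(est, na.rm = TRUE) - cp) / cp, 0.25)
  }
})

test_that("threshold estimation averages the last six reversal excursions", {
  set.seed(44)
  tr <- run_staircase(observer_model(alpha = 0.8, beta = 3, lapse = 0))
  expect_true(tr$complete)
  manual <- mean(utils::tail(
    tr$trials$excursion[tr$trials$is_reversal], 6))
  expect_equal(estimate_threshold(tr), manual)
  expect_equal(tr$threshold_estimate, manual)
  expect_equal(tr$log_threshold, log10(manual))

  # constructed track with known late reversal excursions
  fake <- tr
  fake$reversal_excursions <- c(rep(1, 8), rep(0.5, 6))
  expect_equal(estimate_threshold(fake), 0.5)
  fake$reversal_excursions <- c(rep(1, 8), rep(c(0.4, 0.6), 3))
  expect_equal(estimate_threshold(fake), 0.5)

  short <- run_staircase(NULL, staircase_config(max_trials = 6),
                         responses = TRUE)
  expect_error(estimate_threshold(short), "reversals")
})

test_that("non-compliance rules fire on unstable or late-high tracks", {
  set.seed(45)
  tr <- run_staircase(observer_model(alpha = 0.8, beta = 3, lapse = 0))
  stable <- flag_noncompliance(tr)
  expect_false(stable$flagged)

  # inject a late jump above 50% of the start excursion
  jumped <- tr
  jumped$reversal_excursions[length(jumped$reversal_excursions)] <- 4
  fl <- flag_noncompliance(jumped)
  expect_true(fl$flagged)
  expect_true("late_excursion" %in% fl$rules)

  # lapse-prone observers are flagged more often than clean ones
  set.seed(43)
  rate <- function(lapse) {
    mean(replicate(120, {
      obs <- observer_model(alpha = 0.5, beta = 3, lapse = lapse)
      flag_noncompliance(run_staircase(obs))$flagged
    }))
  }
  expect_gt(rate(0.3), rate(0))
})

test_that("log transform is base 10 and rejects nonpositive input", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(0.1), -1)
  expect_equal(log_transform(6), 0.778, tolerance = 1e-3)
  expect_equal(log_transform(c(1, 10, 100)), c(0, 1, 2))
  expect_error(log_transform(0), "positive")
  expect_error(log_transform(c(1, -2)), "positive")
})
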