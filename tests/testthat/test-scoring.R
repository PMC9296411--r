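make_records <- function(truth, response, task = "discrimination") {
  data.frame(participant_id = "P1", task = task, condition = "speech",
             trial_index = seq_along(truth), truth = truth,
             response = response, correct = truth == response,
             stringsAsFactors = FALSE)
}

test_that("contingency coding partitions trials with the right signal label", {
  r <- make_records(rep(c("different", "same"), each = 18),
                    rep(c("different", "same"), each = 18))
  cc <- code_responses(r, "discrimination")
  expect_equal(cc$hits, 18)
  expect_equal(cc$false_alarms, 0)
  expect_equal(cc$misses + cc$correct_rejections, 18)

  all_diff <- make_records(rep(c("different", "same"), each = 18),
                           rep("different", 36))
  cc2 <- code_responses(all_diff, "discrimination")
  expect_equal(cc2$hits, 18)
  expect_equal(cc2$false_alarms, 18)

  shuffled <- all_diff[sample.int(36), ]
  cc3 <- code_responses(shuffled, "discrimination")
  expect_equal(cc3$hits, cc2$hits)
  expect_equal(cc3$false_alarms, cc2$false_alarms)

  ident <- make_records(rep(c("question", "statement"), each = 18),
                        rep("question", 36), task = "identification")
  cc4 <- code_responses(ident, "identification")
  expect_equal(cc4$hits, 18)
  expect_equal(cc4$false_alarms, 18)

  mixed <- rbind(r, ident)
  expect_error(code_responses(mixed, "discrimination"), "task")
})

test_that("log-linear d-prime matches the inverse-normal formula", {
  # independent recomputation for every possible 18/18 contingency
  for (h in 0:18) for (f in 0:18) {
    cc <- detection_counts(h, 18 - h, f, 18 - f)
    got <- dprime_loglinear(cc)
    H <- (h + 0.5) / 19; F <- (f + 0.5) / 19
    expect_equal(got$d_prime, qnorm(H) - qnorm(F), tolerance = 1e-12)
    expect_equal(got$criterion_c, -(qnorm(H) + qnorm(F)) / 2,
                 tolerance = 1e-12)
    expect_true(got$hit_rate_adj > 0 && got$hit_rate_adj < 1)
    expect_true(got$fa_rate_adj > 0 && got$fa_rate_adj < 1)
    expect_true(is.finite(got$d_prime))
  }
  expect_equal(dprime_loglinear(detection_counts(9, 9, 9, 9))$d_prime, 0)
  expect_equal(dprime_loglinear(detection_counts(9, 9, 9, 9))$criterion_c,
               0)
  expect_equal(dprime_loglinear(detection_counts(18, 0, 0, 18))$d_prime,
               qnorm(18.5 / 19) - qnorm(0.5 / 19), tolerance = 1e-12)
  # antisymmetry under swapping signal and noise rows
  a <- dprime_loglinear(detection_counts(15, 3, 4, 14))$d_prime
  b <- dprime_loglinear(detection_counts(4, 14, 15, 3))$d_prime
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(dprime_loglinear(detection_counts(0, 0, 3, 3)), "signal")
})

test_that("d-prime is monotone in hits and antitone in false alarms", {
  for (f in c(0, 5, 18)) {
    dp <- vapply(0:18, function(h)
      dprime_loglinear(detection_counts(h, 18 - h, f, 18 - f))$d_prime,
      numeric(1))
    expect_true(all(diff(dp) > 0))
  }
  for (h in c(0, 9, 18)) {
    dp <- vapply(0:18, function(f)
      dprime_loglinear(detection_counts(h, 18 - h, f, 18 - f))$d_prime,
      numeric(1))
    expect_true(all(diff(dp) < 0))
  }
})

test_that("per-type proportions expose response biases", {
  allc <- make_records(rep(c("different", "same"), each = 6),
                       rep(c("different", "same"), each = 6))
  pr <- proportions_by_response_type(allc, "discrimination")
  expect_equal(unname(pr$accuracy), c(1, 1))

  biased <- make_records(rep(c("statement", "question"), each = 6),
                         rep("statement", 12), task = "identification")
  pb <- proportions_by_response_type(biased, "identification")
  expect_equal(unname(pb$accuracy["statement"]), 1)
  expect_equal(unname(pb$accuracy["question"]), 0)

  only_q <- make_records(rep("question", 4), rep("question", 4),
                         task = "identification")
  po <- proportions_by_response_type(only_q, "identification")
  expect_equal(po$missing, "statement")
  expect_true(is.na(po$accuracy["statement"]))
})

test_that("an unbiased generator yields symmetric per-type accuracy", {
  set.seed(51)
  pairs <- make_utterance_pairs(18)
  p <- list(id = "X", latent_intonation_d = 1.5, offset_speech = 0,
            offset_music = 0, lapse = 0, criterion = 0)
  diffs <- replicate(150, {
    r <- simulate_perception_responses(
      p, build_identification_trials(pairs))
    pr <- proportions_by_response_type(r, "identification")$accuracy
    pr["question"] - pr["statement"]
  })
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("binomial chance classification uses the exact upper tail", {
  perfect <- binomial_chance_probability(36, 36, 0.5)
  expect_equal(perfect$tail_probability, 0.5^36, tolerance = 1e-15)
  expect_equal(perfect$classification, "above_chance")

  at_mean <- binomial_chance_probability(18, 36, 0.5)
  expect_gt(at_mean$tail_probability, 0.5)
  expect_equal(at_mean$classification, "chance")

  # brute-force enumeration of the cutoff for 36 trials at p = 0.5
  brute_tail <- vapply(0:36, function(k)
    sum(choose(36, k:36)) / 2^36, numeric(1))
  brute_cutoff <- min(which(brute_tail <= 0.05)) - 1
  cls <- vapply(0:36, function(k)
    binomial_chance_probability(k, 36, 0.5)$classification, character(1))
  expect_equal(min(which(cls == "above_chance")) - 1, brute_cutoff)
  # classification monotone in n_correct
  expect_true(all(diff(cls == "above_chance") >= 0))
  tails <- vapply(0:36, function(k)
    binomial_chance_probability(k, 36, 0.5)$tail_probability, numeric(1))
  expect_equal(tails, brute_tail, tolerance = 1e-12)

  expect_error(binomial_chance_probability(3, 6, 0), "p_chance")
  expect_error(binomial_chance_probability(3, 6, 1), "p_chance")
  two <- binomial_chance_probability(18, 36, 0.5,
                                     alternative = "two.sided")
  expect_lte(two$tail_probability, 1)
})
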