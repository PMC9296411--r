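#' Code trial records into a signal-detection contingency
#'
#' In the discrimination task "different" trials are signal trials (correct
#' "different" responses are hits); in the identification and imitation
#' tasks "question" trials are signal trials (correct "question" responses
#' are hits). The four counts partition all trials.
#'
#' @param records Data frame of trial records with columns `truth` and
#'   `response` (and optionally `task`, `participant_id`, `condition`,
#'   which must each be constant if present).
#' @param task `"discrimination"`, `"identification"` or `"imitation"`.
#' @return An object of class `detection_counts`: list with `hits`,
#'   `misses`, `false_alarms`, `correct_rejections`, `n_signal`, `n_noise`,
#'   `signal_label`.
#' @export
code_responses <- function(records,
                           task = c("discrimination", "identification",
                                    "imitation")) {
  task <- match.arg(task)
  stopifnot(is.data.frame(records),
            all(c("truth", "response") %in% names(records)))
  for (col in c("task", "participant_id", "condition")) {
    if (col %in% names(records) && length(unique(records[[col]])) > 1)
      stop(sprintf("records mix several values of `%s`; score one cell at a time",
                   col))
  }
  if ("task" %in% names(records) &&
      nrow(records) > 0 && records$task[1] != task)
    stop(sprintf("records are from task '%s', not '%s'",
                 records$task[1], task))
  signal <- if (task == "discrimination") "different" else "question"
  is_sig <- records$truth == signal
  said_sig <- records$response == signal
  structure(list(
    hits = sum(is_sig & said_sig),
    misses = sum(is_sig & !said_sig),
    false_alarms = sum(!is_sig & said_sig),
    correct_rejections = sum(!is_sig & !said_sig),
    n_signal = sum(is_sig), n_noise = sum(!is_sig),
    signal_label = signal), class = "detection_counts")
}

#' Construct a detection contingency from counts
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative integers.
#' @param signal_label Label of the signal category.
#' @return A `detection_counts` object.
#' @export
detection_counts <- function(hits, misses, false_alarms,
                             correct_rejections,
                             signal_label = "signal") {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(hits = hits, misses = misses, false_alarms = false_alarms,
                 correct_rejections = correct_rejections,
                 n_signal = hits + misses,
                 n_noise = false_alarms + correct_rejections,
                 signal_label = signal_label), class = "detection_counts")
}

#' Sensitivity and bias with the log-linear correction
#'
#' Computes d-prime and criterion c after the log-linear rule: 0.5 is added
#' to each of the four counts (1 to each total), so adjusted hit and
#' false-alarm rates always lie strictly inside (0, 1) and d-prime stays
#' finite even for perfect or empty cells:
#' `H = (hits + 0.5)/(n_signal + 1)`, `F = (FA + 0.5)/(n_noise + 1)`,
#' `d' = z(H) - z(F)`, `c = -(z(H) + z(F))/2`.
#'
#' @param counts A `detection_counts` object (from [code_responses] or
#'   [detection_counts]).
#' @return A list of class `dprime_result` with `d_prime`, `criterion_c`,
#'   `hit_rate_adj`, `fa_rate_adj`.
#' @export
dprime_loglinear <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  if (counts$n_signal < 1 || counts$n_noise < 1)
    stop("need at least one signal and one noise trial")
  h <- (counts$hits + 0.5) / (counts$n_signal + 1)
  f <- (counts$false_alarms + 0.5) / (counts$n_noise + 1)
  zh <- stats::qnorm(h); zf <- stats::qnorm(f)
  structure(list(d_prime = zh - zf, criterion_c = -(zh + zf) / 2,
                 hit_rate_adj = h, fa_rate_adj = f),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("<dprime_result: d' = %.3f, c = %.3f (H %.3f, F %.3f)>\n",
              x$d_prime, x$criterion_c, x$hit_rate_adj, x$fa_rate_adj))
  invisible(x)
}

#' Accuracy by response type
#'
#' Percentage correct computed separately for each truth category — the
#' per-type proportion table a response-bias analysis consumes (e.g.
#' same vs different pairs in discrimination, questions vs statements in
#' identification). Categories with no trials are reported as `NA` and
#' listed in `missing`.
#'
#' @inheritParams code_responses
#' @return A list with `accuracy` (named numeric per truth category) and
#'   `missing` (character vector of absent categories).
#' @export
proportions_by_response_type <- function(records,
                                         task = c("discrimination",
                                                  "identification",
                                                  "imitation")) {
  task <- match.arg(task)
  stopifnot(is.data.frame(records),
            all(c("truth", "response") %in% names(records)))
  categories <- if (task == "discrimination") c("same", "different")
                else c("statement", "question")
  acc <- vapply(categories, function(ct) {
    sel <- records$truth == ct
    if (!any(sel)) return(NA_real_)
    mean(records$response[sel] == records$truth[sel])
  }, numeric(1))
  list(accuracy = acc, missing = categories[is.na(acc)])
}

#' Binomial chance classification of an accuracy rate
#'
#' The probability that an individual's accuracy arises from random guessing:
#' the exact upper-tail probability `P(X >= n_correct)` for
#' `X ~ Binomial(n_trials, p_chance)`. Tail probabilities above 0.05 are
#' classified as consistent with chance, at or below 0.05 as above chance.
#' The default tail is one-sided (is accuracy better than guessing?); a
#' two-sided option doubles the smaller tail.
#'
#' @param n_correct,n_trials Integers, `0 <= n_correct <= n_trials`.
#' @param p_chance Guessing probability (0.5 for binary response sets).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param cutoff Classification cutoff on the tail probability.
#' @return A list of class `chance_assessment` with `n_correct`, `n_trials`,
#'   `p_chance`, `tail_probability`, `classification` (`"chance"` or
#'   `"above_chance"`).
#' @export
binomial_chance_probability <- function(n_correct, n_trials, p_chance = 0.5,
                                        alternative = c("greater",
                                                        "two.sided"),
                                        cutoff = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(n_correct >= 0, n_correct <= n_trials, n_trials >= 1)
  if (p_chance <= 0 || p_chance >= 1)
    stop("p_chance must lie strictly between 0 and 1")
  upper <- stats::pbinom(n_correct - 1, n_trials, p_chance,
                         lower.tail = FALSE)
  tail <- if (alternative == "greater") upper
          else min(1, 2 * min(upper, stats::pbinom(n_correct, n_trials,
                                                   p_chance)))
  structure(list(n_correct = n_correct, n_trials = n_trials,
                 p_chance = p_chance, tail_probability = tail,
                 classification = if (tail > cutoff) "chance"
                                  else "above_chance"),
            class = "chance_assessment")
}
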