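#' Simulated 3AFC observer
#'
#' A Weibull psychometric model for the odd-one-out pitch-direction task:
#' probability correct at excursion `x` semitones is
#' `p(x) = 1/3 + (2/3 - lapse) * (1 - exp(-(x/alpha)^beta))`, rising from the
#' 1/3 guess rate of a three-alternative task to an upper asymptote of
#' `1 - lapse`.
#'
#' @param alpha Psychometric scale in semitones (> 0).
#' @param beta Psychometric slope (> 0).
#' @param lapse Lapse rate in \[0, 2/3).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(alpha = 1, beta = 3, lapse = 0) {
  stopifnot(alpha > 0, beta > 0, lapse >= 0, lapse < 2 / 3)
  structure(list(alpha = alpha, beta = beta, lapse = lapse, guess = 1 / 3),
            class = "observer_model")
}

#' Probability correct of a simulated observer
#'
#' @param obs An [observer_model].
#' @param excursion_st Glide excursion(s) in semitones (>= 0).
#' @return Probability of a correct odd-one-out response, vectorised over
#'   `excursion_st`.
#' @export
observer_p_correct <- function(obs, excursion_st) {
  stopifnot(inherits(obs, "observer_model"), all(excursion_st >= 0))
  obs$guess + (2 / 3 - obs$lapse) *
    (1 - exp(-(excursion_st / obs$alpha) ^ obs$beta))
}

#' Theoretical convergence point of the 2-down-1-up rule
#'
#' A 2-down-1-up staircase converges on the excursion where the observer is
#' correct with probability `2^(-1/2)` (about 70.71%). For the Weibull 3AFC
#' model this point has the closed form
#' `alpha * (-log(1 - (target - 1/3)/(2/3 - lapse)))^(1/beta)`. Used as the
#' analytic oracle for staircase simulations.
#'
#' @param obs An [observer_model].
#' @param target Target probability (default `2^(-1/2)`).
#' @return Excursion in semitones at which `observer_p_correct` equals
#'   `target`.
#' @export
convergence_point <- function(obs, target = 2 ^ (-1 / 2)) {
  stopifnot(inherits(obs, "observer_model"))
  span <- 2 / 3 - obs$lapse
  frac <- (target - obs$guess) / span
  if (frac <= 0 || frac >= 1)
    stop(sprintf(
      "target %.4f unreachable: observer asymptote is %.4f",
      target, obs$guess + span))
  obs$alpha * (-log(1 - frac)) ^ (1 / obs$beta)
}

#' Staircase configuration
#'
#' Defaults encode the pitch-direction threshold procedure: start at 6
#' semitones; step 1 semitone, dropping to 0.1 after 4 reversals and 0.02
#' after 8; stop at 14 reversals; threshold is the mean excursion of the
#' last 6 reversals.
#'
#' @param start_excursion Starting excursion in semitones.
#' @param steps Step sizes in semitones, strictly decreasing.
#' @param step_after Cumulative reversal counts at which each later step
#'   takes over; `steps[i+1]` applies from the first excursion change after
#'   the `step_after[i]`-th reversal completes.
#' @param total_reversals Reversals at which the run terminates.
#' @param estimator_reversals How many final reversals enter the threshold
#'   estimate.
#' @param floor_excursion Smallest allowed excursion (> 0); changes are
#'   clipped here.
#' @param max_trials Safety cap on trial count.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_excursion = 6,
                             steps = c(1, 0.1, 0.02),
                             step_after = c(4, 8),
                             total_reversals = 14,
                             estimator_reversals = 6,
                             floor_excursion = 0.02,
                             max_trials = 400) {
  stopifnot(start_excursion > 0, length(steps) == length(step_after) + 1,
            all(diff(steps) < 0), all(diff(step_after) > 0),
            estimator_reversals <= total_reversals, floor_excursion > 0,
            max_trials > 0)
  structure(list(start_excursion = start_excursion, steps = steps,
                 step_after = step_after, total_reversals = total_reversals,
                 estimator_reversals = estimator_reversals,
                 floor_excursion = floor_excursion, max_trials = max_trials),
            class = "staircase_config")
}

step_for_reversals <- function(config, n_reversals) {
  config$steps[findInterval(n_reversals, config$step_after) + 1L]
}

#' Run a 2-down-1-up adaptive staircase
#'
#' The excursion decreases by the current step after two consecutive correct
#' responses (the consecutive-correct counter resets on each decrease and on
#' each error) and increases by the current step after every error. A
#' reversal is a trial whose excursion change runs opposite to the previous
#' change; the step schedule is keyed to the cumulative reversal count, a new
#' step applying to the first change after the scheduled reversal completes.
#' The run stops at `total_reversals` reversals (or at `max_trials`, flagged
#' incomplete).
#'
#' Responses come either from a simulated [observer_model] (stochastic, uses
#' the current RNG state) or from an explicit logical vector `responses`
#' (deterministic replay, used for hand-traced checks).
#'
#' @param obs An [observer_model], or `NULL` when `responses` is given.
#' @param config A [staircase_config].
#' @param responses Optional logical vector of per-trial correctness
#'   overriding the observer; recycled if shorter than the run.
#' @return An object of class `staircase_track`: a list with `trials` (data
#'   frame: `trial`, `excursion`, `correct`, `step`, `is_reversal`),
#'   `reversal_trials`, `reversal_excursions`, `threshold_estimate`,
#'   `log_threshold` (log10), `complete`, and `config`.
#' @export
run_staircase <- function(obs, config = staircase_config(),
                          responses = NULL) {
  stopifnot(inherits(config, "staircase_config"))
  if (is.null(responses)) stopifnot(inherits(obs, "observer_model"))
  excursion <- config$start_excursion
  n_rev <- 0L
  cc <- 0L                       # consecutive-correct counter
  last_dir <- 0L                 # -1 down, +1 up, 0 none yet
  exc <- cor <- stp <- rev_flag <- numeric(0)
  rev_trials <- integer(0)
  trial <- 0L
  while (n_rev < config$total_reversals && trial < config$max_trials) {
    trial <- trial + 1L
    correct <- if (!is.null(responses)) {
      responses[((trial - 1L) %% length(responses)) + 1L]
    } else {
      stats::runif(1) < observer_p_correct(obs, excursion)
    }
    step <- step_for_reversals(config, n_rev)
    change <- 0
    if (correct) {
      cc <- cc + 1L
      if (cc == 2L) { change <- -step; cc <- 0L }
    } else {
      change <- step
      cc <- 0L
    }
    is_rev <- FALSE
    if (change != 0) {
      dir <- sign(change)
      if (last_dir != 0L && dir != last_dir) {
        is_rev <- TRUE
        n_rev <- n_rev + 1L
        rev_trials <- c(rev_trials, trial)
      }
      last_dir <- dir
    }
    exc <- c(exc, excursion); cor <- c(cor, correct)
    stp <- c(stp, step); rev_flag <- c(rev_flag, is_rev)
    excursion <- max(config$floor_excursion, excursion + change)
  }
  trials <- data.frame(trial = seq_along(exc), excursion = exc,
                       correct = as.logical(cor), step = stp,
                       is_reversal = as.logical(rev_flag))
  complete <- n_rev >= config$total_reversals
  rev_exc <- exc[rev_trials]
  track <- structure(
    list(trials = trials, reversal_trials = rev_trials,
         reversal_excursions = rev_exc,
         threshold_estimate = NA_real_, log_threshold = NA_real_,
         complete = complete, config = config),
    class = "staircase_track")
  if (length(rev_exc) >= config$estimator_reversals) {
    track$threshold_estimate <- estimate_threshold(track)
    track$log_threshold <- log_transform(track$threshold_estimate)
  }
  track
}

#' @export
print.staircase_track <- function(x, ...) {
  cat(sprintf(
    "<staircase_track: %d trials, %d reversals, threshold %.3f st%s>\n",
    nrow(x$trials), length(x$reversal_trials), x$threshold_estimate,
    if (x$complete) "" else " [INCOMPLETE]"))
  invisible(x)
}

#' Reversal-based threshold estimate
#'
#' The arithmetic mean of the excursion sizes presented at the final
#' `estimator_reversals` (default 6) reversal trials.
#'
#' @param track A [staircase_track].
#' @param n_reversals How many final reversals to average (default from the
#'   track's config).
#' @return Threshold in semitones.
#' @export
estimate_threshold <- function(track,
                               n_reversals = track$config$estimator_reversals) {
  stopifnot(inherits(track, "staircase_track"))
  rev_exc <- track$reversal_excursions
  if (length(rev_exc) < n_reversals)
    stop(sprintf("need >= %d reversals, track has %d",
                 n_reversals, length(rev_exc)))
  mean(utils::tail(rev_exc, n_reversals))
}

#' Flag a non-compliant staircase track
#'
#' A surrogate for visual inspection of adaptive tracks: flags a run when
#' (a) the coefficient of variation of the last `estimator_reversals`
#' reversal excursions exceeds `cv_max`, or (b) any of those late reversal
#' excursions exceeds `late_fraction` of the starting excursion — both
#' signatures of attention lapses late in a run. Incomplete runs are always
#' flagged.
#'
#' @param track A [staircase_track].
#' @param cv_max Coefficient-of-variation cutoff for rule (a).
#' @param late_fraction Fraction of `start_excursion` for rule (b).
#' @return A list with `flagged` (logical), `rules` (character vector of
#'   fired rules among `"cv"`, `"late_excursion"`, `"incomplete"`), and
#'   diagnostics `cv` and `late_max`.
#' @export
flag_noncompliance <- function(track, cv_max = 0.5, late_fraction = 0.5) {
  stopifnot(inherits(track, "staircase_track"))
  k <- track$config$estimator_reversals
  late <- utils::tail(track$reversal_excursions, k)
  rules <- character(0)
  cv <- NA_real_; late_max <- NA_real_
  if (!track$complete) rules <- c(rules, "incomplete")
  if (length(late) >= 2) {
    cv <- stats::sd(late) / mean(late)
    late_max <- max(late)
    if (cv > cv_max) rules <- c(rules, "cv")
    if (late_max > late_fraction * track$config$start_excursion)
      rules <- c(rules, "late_excursion")
  }
  list(flagged = length(rules) > 0, rules = rules, cv = cv,
       late_max = late_max)
}

#' Log-transform thresholds
#'
#' Base-10 logarithm, elementwise, as used to bring threshold distributions
#' closer to normal before parametric analysis.
#'
#' @param thresholds Positive numeric vector of thresholds in semitones.
#' @return `log10(thresholds)`.
#' @export
log_transform <- function(thresholds) {
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("thresholds must be positive and finite")
  log10(thresholds)
}

#' Plot a staircase track
#'
#' Excursion by trial with reversals marked and the threshold estimate drawn
#' as a horizontal line — the visual-track analogue used when screening runs
#' by eye.
#'
#' @param x A [staircase_track].
#' @param ... Passed to [graphics::plot].
#' @export
plot.staircase_track <- function(x, ...) {
  graphics::plot(x$trials$trial, x$trials$excursion, type = "b", pch = 19,
                 cex = 0.6, xlab = "Trial", ylab = "Excursion (st)", ...)
  graphics::points(x$reversal_trials, x$reversal_excursions,
                   col = "red", pch = 1, cex = 1.4)
  if (is.finite(x$threshold_estimate))
    graphics::abline(h = x$threshold_estimate, lty = 2, col = "blue")
  invisible(x)
}
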