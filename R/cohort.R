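#' Cohort configuration
#'
#' Describes the simulated participant population: a 2 (group: ASD,
#' control) x 3 (age cohort: child, adolescent, adult) design with
#' per-cell mean log2 pitch-direction thresholds, a Gaussian-copula
#' dependence between log threshold and latent intonation sensitivity, and
#' a music-over-speech discrimination advantage.
#'
#' Default cell means (log2 semitones) encode the effect directions the
#' design is built around: children have higher (worse) thresholds than
#' adolescents and adults, ASD children are worse than control children,
#' and the adult-group difference is small.
#'
#' @param n_per_cell Participants per group x age cell (default 14, i.e.
#'   84 in total).
#' @param group_age_threshold_means Named numeric vector of mean log2
#'   thresholds for cells `"ASD.child"`, `"ASD.adolescent"`, `"ASD.adult"`,
#'   `"control.child"`, `"control.adolescent"`, `"control.adult"`.
#' @param threshold_sd Between-subject SD of log2 threshold (> 0).
#' @param tau_target Target Kendall correlation between log threshold and
#'   intonation sensitivity; must lie in (-1, 0\].
#' @param music_advantage Mean d-prime increment of the music condition
#'   over speech (>= 0).
#' @param intonation_d_mean,intonation_d_sd Mean and SD of the latent
#'   intonation sensitivity (d-prime scale).
#' @param lapse_range Interval from which each participant's lapse rate is
#'   drawn uniformly; within \[0, 0.1\].
#' @param criterion Response criterion of the simulated deciders (0 =
#'   unbiased, the default; a nonzero value generates biased responders for
#'   testing bias analyses).
#' @param seed Integer seed making [generate_cohort] deterministic, or
#'   `NULL` to use the current RNG state.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_cell = 14,
                          group_age_threshold_means = c(
                            ASD.child = 0.26, ASD.adolescent = -1.7,
                            ASD.adult = -1.75,
                            control.child = -1.0,
                            control.adolescent = -1.7,
                            control.adult = -2.0),
                          threshold_sd = 0.8,
                          tau_target = -0.4,
                          music_advantage = 0.3,
                          intonation_d_mean = 2.0,
                          intonation_d_sd = 0.6,
                          lapse_range = c(0, 0.04),
                          criterion = 0,
                          seed = NULL) {
  cells <- c("ASD.child", "ASD.adolescent", "ASD.adult",
             "control.child", "control.adolescent", "control.adult")
  stopifnot(n_per_cell >= 1, threshold_sd > 0,
            all(cells %in% names(group_age_threshold_means)),
            intonation_d_sd > 0,
            length(lapse_range) == 2, lapse_range[1] >= 0,
            lapse_range[2] <= 0.1, lapse_range[1] <= lapse_range[2],
            music_advantage >= 0)
  if (tau_target <= -1 || tau_target > 0)
    stop("tau_target must lie in (-1, 0]")
  structure(list(
    n_per_cell = as.integer(n_per_cell),
    group_age_threshold_means = group_age_threshold_means[cells],
    threshold_sd = threshold_sd, tau_target = tau_target,
    music_advantage = music_advantage,
    intonation_d_mean = intonation_d_mean,
    intonation_d_sd = intonation_d_sd,
    lapse_range = lapse_range, criterion = criterion, seed = seed),
    class = "cohort_config")
}

#' Read a cohort configuration from YAML or JSON
#'
#' Fields missing from the file fall back to the [cohort_config] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$group_age_threshold_means))
    raw$group_age_threshold_means <- unlist(raw$group_age_threshold_means)
  if (!is.null(raw$lapse_range)) raw$lapse_range <- unlist(raw$lapse_range)
  do.call(cohort_config, raw)
}

#' Generate a simulated participant cohort
#'
#' Draws `n_per_cell` participants in each of the six group x age cells.
#' Log2 thresholds and latent intonation sensitivity are generated jointly
#' through a Gaussian copula whose normal-scale correlation
#' `r = sin(pi * tau_target / 2)` yields a population Kendall tau of
#' `tau_target` between the two latents (Kendall tau is invariant to the
#' monotone marginal transforms, so the calibration is exact for any
#' marginals). Each participant also receives condition d-prime offsets
#' (speech 0, music `music_advantage`) and a uniform lapse rate.
#'
#' @param config A [cohort_config].
#' @return A data frame of class `cohort`, one row per participant, with
#'   columns `id`, `group`, `age_cohort`, `latent_log_threshold` (log2
#'   semitones), `threshold_st` (semitones), `latent_intonation_d`,
#'   `offset_speech`, `offset_music`, `lapse`, `criterion`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cells <- names(config$group_age_threshold_means)
  mu <- config$group_age_threshold_means
  n <- config$n_per_cell * length(cells)
  r <- sin(pi * config$tau_target / 2)
  cell <- rep(cells, each = config$n_per_cell)
  parts <- strsplit(cell, ".", fixed = TRUE)
  log_thr <- mu[cell] + config$threshold_sd * stats::rnorm(n)
  # Normal score of the threshold under its population marginal (an
  # equal-weight mixture of the six cell normals), so the Gaussian copula
  # linking threshold and sensitivity yields Kendall tau = tau_target over
  # the whole cohort, not just within cells.
  u <- rowMeans(vapply(mu, function(m)
    stats::pnorm(log_thr, mean = m, sd = config$threshold_sd),
    numeric(n)))
  z1 <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  z2 <- r * z1 + sqrt(1 - r ^ 2) * stats::rnorm(n)
  d <- config$intonation_d_mean + config$intonation_d_sd * z2
  out <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    group = vapply(parts, `[`, character(1), 1),
    age_cohort = vapply(parts, `[`, character(1), 2),
    latent_log_threshold = unname(log_thr),
    threshold_st = unname(2 ^ log_thr),
    latent_intonation_d = unname(d),
    offset_speech = 0,
    offset_music = config$music_advantage,
    lapse = stats::runif(n, config$lapse_range[1], config$lapse_range[2]),
    criterion = config$criterion,
    stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  attr(out, "config") <- config
  out
}

participant_row <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    return(as.list(p))
  }
  stopifnot(is.list(p))
  p
}

#' Simulate perception-task responses for one participant
#'
#' Trial-level responses from an equal-variance signal-detection decider:
#' on signal trials the decision variable is N(d, 1), on noise trials
#' N(0, 1), with d the participant's latent intonation sensitivity plus the
#' condition offset; the decider answers "signal" when the variable exceeds
#' `d/2 + criterion` (criterion 0 = unbiased). With probability `lapse` the
#' response is instead uniform random. Uses the current RNG state.
#'
#' @param p One cohort row (single-row data frame or list).
#' @param trial_list A `trial_list` from [build_discrimination_trials] or
#'   [build_identification_trials].
#' @return A data frame of response records: `participant_id`, `task`,
#'   `condition`, `trial_index`, `truth`, `response`, `correct`.
#' @export
simulate_perception_responses <- function(p, trial_list) {
  stopifnot(inherits(trial_list, "trial_list"))
  p <- participant_row(p)
  cond <- trial_list$condition
  offset <- switch(cond,
                   speech = p$offset_speech,
                   music = p$offset_music,
                   stop("unknown condition: ", cond))
  d <- p$latent_intonation_d + offset
  signal <- if (trial_list$task == "discrimination") "different"
            else "question"
  truths <- trial_list$trials$truth
  labels <- if (trial_list$task == "discrimination")
    c("same", "different") else c("statement", "question")
  n <- length(truths)
  is_sig <- truths == signal
  evidence <- stats::rnorm(n, mean = ifelse(is_sig, d, 0), sd = 1)
  said_sig <- evidence > d / 2 + (p$criterion %||% 0)
  lapsed <- stats::runif(n) < p$lapse
  said_sig[lapsed] <- stats::runif(sum(lapsed)) < 0.5
  response <- ifelse(said_sig, signal, setdiff(labels, signal))
  data.frame(
    participant_id = p$id %||% "P000",
    task = trial_list$task, condition = cond,
    trial_index = trial_list$trials$trial_index,
    truth = truths, response = response,
    correct = response == truths, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form sign-match probability of the imitation model
#'
#' The probability that a simulated imitation carries the same glide sign
#' as its model: `lapse/2 + (1 - lapse) * pnorm(d / sqrt(2))`, the
#' two-alternative percent correct of an equal-variance decider with
#' sensitivity `d`, mixed with lapse-rate guessing.
#'
#' @param d Latent sensitivity (d-prime scale).
#' @param lapse Lapse rate.
#' @return Probability in (0, 1).
#' @export
imitation_match_probability <- function(d, lapse = 0) {
  lapse / 2 + (1 - lapse) * stats::pnorm(d / sqrt(2))
}

#' Simulate one imitation production
#'
#' The produced final-word glide matches the model's sign with the
#' closed-form probability of [imitation_match_probability] evaluated at
#' the participant's latent intonation sensitivity; its magnitude is
#' log-normal around the model magnitude with log-scale SD `sigma_mag`.
#' Uses the current RNG state.
#'
#' @param p One cohort row.
#' @param spec The model [utterance_spec]; must have a nonzero final glide.
#' @param sigma_mag Log-scale SD of the produced glide magnitude.
#' @return A `glide_measurement` for the simulated production.
#' @export
simulate_imitation <- function(p, spec, sigma_mag = 0.3) {
  stopifnot(inherits(spec, "utterance_spec"))
  if (spec$final_glide_hz == 0)
    stop("model glide is zero: ambiguous model")
  p <- participant_row(p)
  p_match <- imitation_match_probability(p$latent_intonation_d, p$lapse)
  s <- sign(spec$final_glide_hz) *
    (if (stats::runif(1) < p_match) 1 else -1)
  mag <- abs(spec$final_glide_hz) * exp(stats::rnorm(1, 0, sigma_mag))
  glide <- s * mag
  structure(list(glide_hz = glide, interval = NULL,
                 n_voiced_frames = NA_integer_,
                 label = classify_sentence_type_hz(glide)),
            class = "glide_measurement")
}
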