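#' Experiment configuration
#'
#' Bundles everything one in-silico replication needs: the cohort, the
#' staircase procedure, the stimulus set and the seed.
#'
#' @param cohort A [cohort_config].
#' @param staircase A [staircase_config].
#' @param n_pairs Number of statement-question pairs (default 18, giving
#'   36 trials per task block).
#' @param observer_beta Psychometric slope of the simulated staircase
#'   observers.
#' @param seed Integer seed for the whole run.
#' @param output_dir Directory for CSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @param write_plots Write one PNG staircase-track plot per participant.
#' @param write_audio Render and write the stimulus WAV files (speech
#'   proxies and musical analogues for each pair).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              staircase = staircase_config(),
                              n_pairs = 18, observer_beta = 3,
                              seed = 1, output_dir = NULL,
                              write_plots = FALSE, write_audio = FALSE) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(staircase, "staircase_config"),
            n_pairs >= 1, observer_beta > 0)
  structure(list(cohort = cohort, staircase = staircase,
                 n_pairs = as.integer(n_pairs),
                 observer_beta = observer_beta, seed = as.integer(seed),
                 output_dir = output_dir, write_plots = write_plots,
                 write_audio = write_audio),
            class = "experiment_config")
}

# Observer whose 70.71%-correct point sits exactly at the participant's
# latent threshold, so the staircase targets the latent value.
observer_for_threshold <- function(threshold_st, beta, lapse) {
  target <- 2 ^ (-1 / 2)
  span <- 2 / 3 - lapse
  scale <- (-log(1 - (target - 1 / 3) / span)) ^ (1 / beta)
  observer_model(alpha = threshold_st / scale, beta = beta, lapse = lapse)
}

score_participant_cell <- function(records, task) {
  counts <- code_responses(records, task)
  dp <- dprime_loglinear(counts)
  props <- proportions_by_response_type(records, task)
  chance <- binomial_chance_probability(sum(records$correct), nrow(records))
  data.frame(
    task = task, condition = records$condition[1],
    n_trials = nrow(records), n_correct = sum(records$correct),
    accuracy = mean(records$correct),
    hits = counts$hits, false_alarms = counts$false_alarms,
    d_prime = dp$d_prime, criterion_c = dp$criterion_c,
    acc_type1 = props$accuracy[1], acc_type2 = props$accuracy[2],
    chance_tail_p = chance$tail_probability,
    chance_class = chance$classification,
    stringsAsFactors = FALSE)
}

#' Run a full in-silico experiment
#'
#' Generates a cohort, then per participant: runs the adaptive pitch
#' threshold staircase (with a simulated observer whose convergence point
#' is the participant's latent threshold), simulates the speech and music
#' discrimination blocks, the identification block and the imitation
#' block, scores everything (log-linear d-prime, per-type proportions,
#' binomial chance classification), screens staircase tracks for
#' non-compliance, and assembles summary tables plus a parameter-recovery
#' report. Fully reproducible under a fixed seed. Task order per
#' participant is a seeded permutation (recorded, behaviourally inert).
#'
#' @param config An [experiment_config].
#' @return (Invisibly) a list of class `experiment_results` with elements
#'   `cohort`, `tracks`, `staircase` (per-participant estimates data
#'   frame), `responses` (all trial records), `scores` (per participant x
#'   task x condition), `task_order`, `summary`, `recovery`, and `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- NULL                  # one seed governs the whole run
  cohort <- generate_cohort(cohort_cfg)
  pairs <- make_utterance_pairs(config$n_pairs)
  tasks <- c("discrimination_speech", "discrimination_music",
             "identification", "imitation")

  tracks <- list()
  stair_rows <- resp_list <- score_list <- order_rows <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    obs <- observer_for_threshold(p$threshold_st, config$observer_beta,
                                  p$lapse)
    track <- run_staircase(obs, config$staircase)
    compliance <- flag_noncompliance(track)
    tracks[[p$id]] <- track
    stair_rows[[i]] <- data.frame(
      participant_id = p$id, group = p$group, age_cohort = p$age_cohort,
      threshold_true = p$threshold_st,
      threshold_estimate = track$threshold_estimate,
      log10_threshold = track$log_threshold,
      n_trials = nrow(track$trials), complete = track$complete,
      noncompliant = compliance$flagged,
      noncompliance_rules = paste(compliance$rules, collapse = ";"),
      stringsAsFactors = FALSE)
    order_rows[[i]] <- data.frame(
      participant_id = p$id,
      task_order = paste(sample(tasks), collapse = ","),
      stringsAsFactors = FALSE)

    blocks <- list(
      simulate_perception_responses(
        p, build_discrimination_trials(pairs, "speech")),
      simulate_perception_responses(
        p, build_discrimination_trials(pairs, "music")),
      simulate_perception_responses(
        p, build_identification_trials(pairs)))

    imit_specs <- unlist(lapply(pairs, function(pr)
      list(pr$statement, pr$question)), recursive = FALSE)
    imit_specs <- imit_specs[sample.int(length(imit_specs))]
    imit <- do.call(rbind, lapply(seq_along(imit_specs), function(k) {
      spec <- imit_specs[[k]]
      g <- simulate_imitation(p, spec)
      sc <- score_imitation(spec, g)
      truth <- spec$sentence_type
      data.frame(participant_id = p$id, task = "imitation",
                 condition = "n/a", trial_index = k, truth = truth,
                 response = if (sc$correct) truth else
                   setdiff(c("statement", "question"), truth),
                 correct = sc$correct, glide_hz = g$glide_hz,
                 stringsAsFactors = FALSE)
    }))
    blocks <- lapply(blocks, function(b) { b$glide_hz <- NA_real_; b })
    resp <- rbind(do.call(rbind, blocks), imit)
    resp_list[[i]] <- resp

    cells <- split(resp, paste(resp$task, resp$condition))
    sc <- do.call(rbind, lapply(cells, function(cell)
      score_participant_cell(cell, cell$task[1])))
    sc <- cbind(data.frame(participant_id = p$id, group = p$group,
                           age_cohort = p$age_cohort,
                           stringsAsFactors = FALSE), sc)
    score_list[[i]] <- sc
  }
  staircase_df <- do.call(rbind, stair_rows)
  responses <- do.call(rbind, resp_list)
  scores <- do.call(rbind, score_list)
  rownames(scores) <- rownames(responses) <- NULL
  summary_tab <- summarize_cohort(scores)

  results <- structure(
    list(cohort = cohort, tracks = tracks, staircase = staircase_df,
         responses = responses, scores = scores,
         task_order = do.call(rbind, order_rows),
         summary = summary_tab, recovery = NULL, config = config),
    class = "experiment_results")
  results$recovery <- recovery_report(results, config)
  if (!is.null(config$output_dir)) write_results(results)
  invisible(results)
}

#' Parameter-recovery report
#'
#' Compares what the pipeline estimated with what the generator was told
#' to produce: per-cell mean log2 thresholds (non-compliant tracks
#' excluded), the Kendall tau between estimated log threshold and each
#' participant's d-prime pooled over all four task blocks (every block is
#' driven by the same latent sensitivity, so pooling gives its least
#' attenuated estimate), the mean music-minus-speech d-prime difference,
#' and the identification-imitation accuracy correlation (expected
#' positive: both tasks share the same latent). Each estimate carries a
#' Monte-Carlo standard error; estimates outside their tolerance are
#' flagged.
#'
#' @param results An `experiment_results` list from [run_experiment].
#' @param config The [experiment_config] used (defaults to the one stored
#'   in `results`).
#' @param tau_tol Tolerance on the recovered threshold-sensitivity tau.
#' @param mean_tol Tolerance (log2 units) on per-cell threshold means.
#' @return A list of class `recovery_report` with one element per
#'   generating parameter (`estimate`, `generating`, `se`, `flagged`).
#' @export
recovery_report <- function(results, config = results$config,
                            tau_tol = 0.15, mean_tol = 1.0) {
  stopifnot(inherits(results, "experiment_results"))
  for (need in c("staircase", "scores"))
    if (is.null(results[[need]]))
      stop("results are missing stage output: ", need)
  st <- results$staircase
  keep <- !st$noncompliant & is.finite(st$threshold_estimate)
  st_ok <- st[keep, ]
  cellkey <- paste(st_ok$group, st_ok$age_cohort, sep = ".")
  gen_means <- config$cohort$group_age_threshold_means
  cell_est <- vapply(names(gen_means), function(cl) {
    v <- log2(st_ok$threshold_estimate[cellkey == cl])
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  cell_se <- vapply(names(gen_means), function(cl) {
    v <- log2(st_ok$threshold_estimate[cellkey == cl])
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }, numeric(1))

  sc <- results$scores
  disc <- sc[sc$task == "discrimination", ]
  pooled_d <- tapply(sc$d_prime, sc$participant_id, mean)
  thr <- st$log10_threshold[match(names(pooled_d), st$participant_id)]
  ok <- is.finite(thr) & is.finite(pooled_d)
  n_tau <- sum(ok)
  tau_hat <- kendall_tau(thr[ok], as.numeric(pooled_d)[ok])
  tau_se <- sqrt(2 * (2 * n_tau + 5) / (9 * n_tau * (n_tau - 1)))

  wide <- split(disc$d_prime, disc$condition)
  ids_m <- disc$participant_id[disc$condition == "music"]
  ids_s <- disc$participant_id[disc$condition == "speech"]
  diff_ms <- wide$music[order(ids_m)] - wide$speech[order(ids_s)]
  diff_hat <- mean(diff_ms)
  diff_se <- stats::sd(diff_ms) / sqrt(length(diff_ms))

  ident <- sc[sc$task == "identification", ]
  imit <- sc[sc$task == "imitation", ]
  common <- intersect(ident$participant_id, imit$participant_id)
  ii_tau <- kendall_tau(
    ident$d_prime[match(common, ident$participant_id)],
    imit$d_prime[match(common, imit$participant_id)])

  structure(list(
    threshold_cell_means = list(
      estimate = cell_est, generating = gen_means, se = cell_se,
      flagged = any(abs(cell_est - gen_means) > mean_tol, na.rm = TRUE)),
    threshold_dprime_tau = list(
      estimate = tau_hat, generating = config$cohort$tau_target,
      se = tau_se,
      flagged = is.na(tau_hat) ||
        abs(tau_hat - config$cohort$tau_target) > tau_tol),
    music_minus_speech_dprime = list(
      estimate = diff_hat, generating = config$cohort$music_advantage,
      se = diff_se,
      flagged = (config$cohort$music_advantage > 0) && (diff_hat <= 0)),
    identification_imitation_tau = list(
      estimate = ii_tau, generating = "positive (shared latent)",
      se = sqrt(2 * (2 * length(common) + 5) /
                  (9 * length(common) * (length(common) - 1))),
      flagged = is.na(ii_tau) || ii_tau <= 0),
    n_participants = nrow(st), n_excluded_noncompliant = sum(!keep)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  threshold-d' tau: %.3f (target %.2f, se %.3f)%s\n",
              x$threshold_dprime_tau$estimate,
              x$threshold_dprime_tau$generating,
              x$threshold_dprime_tau$se,
              if (x$threshold_dprime_tau$flagged) " [FLAGGED]" else ""))
  cat(sprintf("  music - speech d': %.3f (target %.2f, se %.3f)%s\n",
              x$music_minus_speech_dprime$estimate,
              x$music_minus_speech_dprime$generating,
              x$music_minus_speech_dprime$se,
              if (x$music_minus_speech_dprime$flagged) " [FLAGGED]" else ""))
  cat(sprintf("  identification-imitation tau: %.3f (expected > 0)%s\n",
              x$identification_imitation_tau$estimate,
              if (x$identification_imitation_tau$flagged)
                " [FLAGGED]" else ""))
  cat(sprintf("  participants: %d (%d non-compliant excluded)\n",
              x$n_participants, x$n_excluded_noncompliant))
  invisible(x)
}

write_results <- function(results) {
  config <- results$config
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(results$cohort, out("cohort.csv"), row.names = FALSE)
  utils::write.csv(results$staircase, out("staircase.csv"),
                   row.names = FALSE)
  utils::write.csv(results$responses, out("responses.csv"),
                   row.names = FALSE)
  utils::write.csv(results$scores, out("scores.csv"), row.names = FALSE)
  utils::write.csv(results$summary$table, out("summary.csv"),
                   row.names = FALSE)
  utils::write.csv(results$task_order, out("task_order.csv"),
                   row.names = FALSE)
  trk <- do.call(rbind, lapply(names(results$tracks), function(id)
    cbind(participant_id = id, results$tracks[[id]]$trials)))
  utils::write.csv(trk, out("staircase_trials.csv"), row.names = FALSE)
  rec <- rapply(unclass(results$recovery), function(v) v, how = "list")
  jsonlite::write_json(rec, out("recovery.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (isTRUE(config$write_plots)) {
    dir.create(out("tracks"), showWarnings = FALSE)
    for (id in names(results$tracks)) {
      grDevices::png(out(file.path("tracks", paste0(id, ".png"))),
                     width = 700, height = 400)
      plot(results$tracks[[id]], main = id)
      grDevices::dev.off()
    }
  }
  if (isTRUE(config$write_audio)) {
    dir.create(out("audio"), showWarnings = FALSE)
    set.seed(config$seed)
    pairs <- make_utterance_pairs(config$n_pairs)
    for (pr in pairs) {
      for (memb in c("statement", "question")) {
        contour <- make_utterance_contour(pr[[memb]])
        sp <- render_speech_proxy(contour)
        mu <- normalize_peak(render_musical_analogue(contour), sp)
        base <- paste0(pr[[memb]]$pair_id, "_", memb)
        write_wav(sp, out(file.path("audio",
                                    paste0(base, "_speech.wav"))))
        write_wav(mu, out(file.path("audio",
                                    paste0(base, "_music.wav"))))
      }
    }
  }
  invisible(results)
}
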