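#' Make a set of statement-question utterance pairs
#'
#' Convenience generator for `n_pairs` cross-spliced pairs with glide
#' magnitudes drawn uniformly from `glide_range` (statement member gets the
#' negative glide, question member the positive one) and mild variation in
#' stem onset F0. Uses the current RNG state.
#'
#' @param n_pairs Number of pairs (default 18).
#' @param glide_range Range of |final glide| in Hz.
#' @param stem_start_range Range of stem onset F0 in Hz.
#' @return A list of `n_pairs` elements, each a list with members
#'   `statement` and `question` ([utterance_spec]s sharing stem parameters
#'   and `pair_id`).
#' @export
make_utterance_pairs <- function(n_pairs = 18, glide_range = c(30, 80),
                                 stem_start_range = c(180, 260)) {
  stopifnot(n_pairs >= 1)
  lapply(seq_len(n_pairs), function(i) {
    g <- stats::runif(1, glide_range[1], glide_range[2])
    f0 <- stats::runif(1, stem_start_range[1], stem_start_range[2])
    id <- sprintf("pair%02d", i)
    list(
      statement = utterance_spec("statement", -g, stem_start_f0 = f0,
                                 pair_id = id),
      question = utterance_spec("question", g, stem_start_f0 = f0,
                                pair_id = id))
  })
}

new_trial_list <- function(task, condition, trials, isi_ms = 750,
                           iti_ms = 2000) {
  trials$trial_index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  structure(list(task = task, condition = condition, trials = trials,
                 isi_ms = isi_ms, iti_ms = iti_ms), class = "trial_list")
}

#' @export
print.trial_list <- function(x, ...) {
  cat(sprintf("<trial_list: %s/%s, %d trials (ISI %d ms, ITI %d ms)>\n",
              x$task, x$condition, nrow(x$trials), x$isi_ms, x$iti_ms))
  invisible(x)
}

#' Build a same-different discrimination trial list
#'
#' Two trials per statement-question pair: one "different" trial (statement
#' vs question member) and one "same" trial (one member repeated). Which
#' member is repeated is balanced across pairs — half statement-same, half
#' question-same — so response type is not confounded with sentence type.
#' Trial order is shuffled with the current RNG state.
#'
#' @param pairs List of pairs from [make_utterance_pairs] (or the same
#'   shape).
#' @param condition `"speech"` or `"music"`.
#' @param strict_balance If `TRUE`, an odd number of pairs is an error;
#'   otherwise the same-trial split is floor/ceiling.
#' @param isi_ms,iti_ms Interstimulus and intertrial intervals in ms.
#' @return A `trial_list` whose `trials` data frame has columns `pair_id`,
#'   `truth` (`"same"`/`"different"`), `stim_a`, `stim_b` (sentence types
#'   presented), `trial_index`.
#' @export
build_discrimination_trials <- function(pairs,
                                        condition = c("speech", "music"),
                                        strict_balance = FALSE,
                                        isi_ms = 750, iti_ms = 2000) {
  condition <- match.arg(condition)
  n <- length(pairs)
  stopifnot(n >= 1)
  if (strict_balance && n %% 2 != 0)
    stop("strict balancing of same-trial types needs an even pair count")
  ids <- vapply(pairs, function(p) p$statement$pair_id, character(1))
  n_stmt_same <- floor(n / 2)
  same_member <- sample(rep(c("statement", "question"),
                            c(n_stmt_same, n - n_stmt_same)))
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      pair_id = ids[i],
      truth = c("different", "same"),
      stim_a = c("statement", same_member[i]),
      stim_b = c("question", same_member[i]),
      stringsAsFactors = FALSE)
  }))
  rows <- rows[sample.int(nrow(rows)), ]
  new_trial_list("discrimination", condition, rows, isi_ms, iti_ms)
}

#' Build an identification trial list
#'
#' Every pair contributes its statement and its question once, presented
#' singly; order shuffled with the current RNG state.
#'
#' @inheritParams build_discrimination_trials
#' @return A `trial_list` whose `trials` data frame has columns `pair_id`,
#'   `truth` (`"statement"`/`"question"`), `trial_index`.
#' @export
build_identification_trials <- function(pairs, isi_ms = 750,
                                        iti_ms = 2000) {
  n <- length(pairs)
  stopifnot(n >= 1)
  ids <- vapply(pairs, function(p) p$statement$pair_id, character(1))
  rows <- data.frame(
    pair_id = rep(ids, each = 2),
    truth = rep(c("statement", "question"), n),
    stringsAsFactors = FALSE)
  rows <- rows[sample.int(nrow(rows)), ]
  new_trial_list("identification", "speech", rows, isi_ms, iti_ms)
}
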