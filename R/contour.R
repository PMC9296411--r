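#' Fundamental-frequency contour
#'
#' The common currency between stimulus synthesis and acoustic analysis: a
#' time-stamped F0 trajectory together with syllable intervals and the
#' annotated final-word interval. F0 values of 0 (or `NA`) mark unvoiced
#' frames; voiced values must be positive.
#'
#' @param times Numeric vector of time stamps in seconds, strictly increasing.
#' @param f0 Numeric vector of F0 values in Hz, same length as `times`;
#'   0 or `NA` marks unvoiced frames.
#' @param syllable_intervals Two-column matrix (or data.frame) of
#'   `(start, end)` times in seconds, non-overlapping and ordered.
#' @param final_word_interval Length-2 numeric `(start, end)` in seconds, or
#'   `NULL` when no final word is annotated.
#'
#' @return An object of class `f0_contour`.
#' @export
f0_contour <- function(times, f0, syllable_intervals = NULL,
                       final_word_interval = NULL) {
  stopifnot(length(times) == length(f0), length(times) >= 1)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  voiced <- !is.na(f0) & f0 != 0
  if (any(f0[voiced] < 0)) stop("voiced f0 values must be positive")
  if (!is.null(syllable_intervals)) {
    syllable_intervals <- as.matrix(syllable_intervals)
    stopifnot(ncol(syllable_intervals) == 2)
    if (any(syllable_intervals[, 2] <= syllable_intervals[, 1]))
      stop("syllable intervals must have end > start")
    if (nrow(syllable_intervals) > 1) {
      s <- syllable_intervals
      if (any(s[-1, 1] < s[-nrow(s), 2] - 1e-9))
        stop("syllable intervals must be ordered and non-overlapping")
    }
  }
  if (!is.null(final_word_interval)) {
    stopifnot(length(final_word_interval) == 2)
    if (final_word_interval[1] < times[1] - 1e-9 ||
        final_word_interval[2] > times[length(times)] + 1e-9)
      stop("final_word_interval must lie within the contour time range")
  }
  structure(
    list(times = as.numeric(times), f0 = as.numeric(f0),
         syllable_intervals = syllable_intervals,
         final_word_interval = final_word_interval),
    class = "f0_contour")
}

#' @export
print.f0_contour <- function(x, ...) {
  voiced <- !is.na(x$f0) & x$f0 > 0
  cat(sprintf("<f0_contour: %d frames over %.3f s, %d voiced",
              length(x$times), diff(range(x$times)), sum(voiced)))
  if (any(voiced))
    cat(sprintf(", F0 %.1f-%.1f Hz", min(x$f0[voiced]), max(x$f0[voiced])))
  cat(">\n")
  invisible(x)
}

#' Pseudo-utterance specification
#'
#' Describes one member of a statement-question pair: a stem of declining
#' syllables followed by a final word carrying the terminal glide. Statement
#' and question members that share a `pair_id` and stem parameters have
#' sample-identical stems when rendered, emulating cross-spliced stimulus
#' pairs whose members begin with the same stem and differ only in the final
#' word.
#'
#' @param sentence_type `"statement"` or `"question"`.
#' @param final_glide_hz Signed final-word glide in Hz. Must be negative
#'   (terminal fall) for statements and positive (terminal rise) for
#'   questions.
#' @param stem_syllables Number of stem syllables before the final word.
#' @param stem_start_f0 F0 in Hz at utterance onset.
#' @param declination Stem F0 drift in Hz/s; must be <= 0.
#' @param syllable_duration Duration of each syllable (and of the final word)
#'   in seconds.
#' @param pair_id Token identifying the statement-question pair.
#'
#' @return An object of class `utterance_spec`.
#' @export
utterance_spec <- function(sentence_type = c("statement", "question"),
                           final_glide_hz,
                           stem_syllables = 3,
                           stem_start_f0 = 220,
                           declination = -10,
                           syllable_duration = 0.25,
                           pair_id = "pair01") {
  sentence_type <- match.arg(sentence_type)
  stopifnot(stem_syllables >= 1, stem_start_f0 > 0, syllable_duration > 0)
  if (declination > 0) stop("`declination` must be <= 0 (Hz/s downtrend)")
  expected_sign <- if (sentence_type == "statement") -1 else 1
  if (sign(final_glide_hz) != expected_sign)
    stop(sprintf("final_glide_hz must be %s for a %s",
                 if (expected_sign < 0) "negative" else "positive",
                 sentence_type))
  structure(
    list(sentence_type = sentence_type, stem_syllables = stem_syllables,
         stem_start_f0 = stem_start_f0, declination = declination,
         final_glide_hz = final_glide_hz,
         syllable_duration = syllable_duration, pair_id = pair_id),
    class = "utterance_spec")
}

#' Build the F0 contour of a pitch glide tone
#'
#' Constructs a log-linear glide geometrically centred on `center_hz` and
#' spanning `excursion_st` semitones end to end, i.e. running from
#' `center * 2^(-e/24)` to `center * 2^(+e/24)` (reversed for `"down"`).
#' Geometric centring keeps upward and downward glides symmetric in
#' log frequency.
#'
#' @param center_hz Centre frequency in Hz (> 0).
#' @param excursion_st End-to-end excursion in semitones (>= 0); 0 gives a
#'   steady tone.
#' @param direction `"up"` or `"down"`.
#' @param duration_s Tone duration in seconds.
#' @param hop_s Sampling interval of the returned contour in seconds.
#'
#' @return An [f0_contour] with a single syllable interval covering the tone.
#' @export
make_glide_contour <- function(center_hz = 500, excursion_st = 6,
                               direction = c("up", "down"),
                               duration_s = 0.6, hop_s = 0.005) {
  direction <- match.arg(direction)
  stopifnot(center_hz > 0, excursion_st >= 0, duration_s > 0)
  times <- seq(0, duration_s, by = hop_s)
  if (times[length(times)] < duration_s) times <- c(times, duration_s)
  frac <- times / duration_s                 # 0 -> 1
  semis <- (frac - 0.5) * excursion_st       # -e/2 -> +e/2 semitones
  if (direction == "down") semis <- -semis
  f0 <- center_hz * 2 ^ (semis / 12)
  f0_contour(times, f0,
             syllable_intervals = matrix(c(0, duration_s), ncol = 2),
             final_word_interval = c(0, duration_s))
}

#' Build an odd-one-out glide triplet
#'
#' Three glide tones sharing centre frequency, excursion and duration; two
#' move in `target_direction` and one (the odd-one-out) moves oppositely.
#' The position of the odd tone is uniform over the three slots.
#'
#' @param target_direction Direction of the two matching tones
#'   (`"up"` or `"down"`); the odd tone takes the opposite direction.
#' @param excursion_st End-to-end excursion in semitones.
#' @param center_hz Centre frequency in Hz.
#' @param duration_s Tone duration in seconds.
#'
#' @return A list with `contours` (list of three [f0_contour]s) and
#'   `odd_index` (position of the odd-one-out, in 1..3).
#' @export
make_triplet <- function(target_direction = c("up", "down"),
                         excursion_st = 6, center_hz = 500,
                         duration_s = 0.6) {
  target_direction <- match.arg(target_direction)
  odd_dir <- if (target_direction == "up") "down" else "up"
  odd_index <- sample.int(3L, 1L)
  contours <- lapply(1:3, function(i) {
    d <- if (i == odd_index) odd_dir else target_direction
    make_glide_contour(center_hz, excursion_st, d, duration_s)
  })
  list(contours = contours, odd_index = odd_index)
}

#' Build the F0 contour of a pseudo-utterance
#'
#' The stem follows a linear declination from `stem_start_f0`; the final word
#' is a linear glide (in Hz) of `final_glide_hz` starting from the stem's
#' final F0. Statement and question members sharing stem parameters have
#' identical contours over the stem, so rendered pairs differ only in the
#' final word.
#'
#' @param spec An [utterance_spec].
#' @param hop_s Sampling interval of the returned contour in seconds.
#'
#' @return An [f0_contour] with one interval per syllable plus the final
#'   word; `final_word_interval` covers the final word.
#' @export
make_utterance_contour <- function(spec, hop_s = 0.005) {
  stopifnot(inherits(spec, "utterance_spec"))
  n_syll <- spec$stem_syllables
  dur_syll <- spec$syllable_duration
  stem_dur <- n_syll * dur_syll
  total_dur <- stem_dur + dur_syll           # final word = one more syllable
  times <- seq(0, total_dur, by = hop_s)
  if (times[length(times)] < total_dur) times <- c(times, total_dur)
  stem_end_f0 <- spec$stem_start_f0 + spec$declination * stem_dur
  f0 <- ifelse(times <= stem_dur,
               spec$stem_start_f0 + spec$declination * times,
               stem_end_f0 + spec$final_glide_hz *
                 (times - stem_dur) / dur_syll)
  if (any(f0 <= 0))
    stop("contour would cross 0 Hz; adjust declination/glide/start F0")
  syl <- cbind(seq(0, stem_dur, by = dur_syll),
               seq(dur_syll, total_dur, by = dur_syll))
  f0_contour(times, f0, syllable_intervals = syl,
             final_word_interval = c(stem_dur, total_dur))
}
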