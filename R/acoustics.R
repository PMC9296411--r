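#' F0 extraction parameters
#'
#' @param frame_length_s Analysis frame length in seconds (must cover at
#'   least two periods of `fmin`).
#' @param hop_s Frame hop in seconds.
#' @param fmin,fmax F0 search band in Hz.
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @param silence_rms Frames with RMS below this are unvoiced outright.
#' @return A list of class `f0_params`.
#' @export
f0_params <- function(frame_length_s = 0.04, hop_s = 0.01,
                      fmin = 75, fmax = 600,
                      voicing_threshold = 0.5, silence_rms = 1e-4) {
  stopifnot(fmin > 0, fmin < fmax, hop_s > 0)
  if (frame_length_s < 2 / fmin)
    stop("frame_length_s must be at least 2/fmin")
  structure(list(frame_length_s = frame_length_s, hop_s = hop_s,
                 fmin = fmin, fmax = fmax,
                 voicing_threshold = voicing_threshold,
                 silence_rms = silence_rms), class = "f0_params")
}

# Parabolic interpolation of a discrete peak at index i of y; returns the
# fractional offset in (-0.5, 0.5).
parabolic_offset <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(0)
  0.5 * (y[i - 1] - y[i + 1]) / denom
}

#' Autocorrelation F0 tracking
#'
#' Frame-wise pitch estimation: each frame's normalized autocorrelation is
#' searched for its highest peak in the lag band corresponding to
#' \[`fmin`, `fmax`\]; the peak lag is refined by parabolic interpolation and
#' inverted to Hz. Frames whose best normalized peak falls below
#' `voicing_threshold`, or whose RMS is below `silence_rms`, are marked
#' unvoiced (F0 = 0).
#'
#' @param audio An [audio_buffer].
#' @param params An [f0_params].
#' @return An [f0_contour] with one frame per hop; `times` are frame
#'   centres.
#' @export
extract_f0 <- function(audio, params = f0_params()) {
  stopifnot(inherits(audio, "audio_buffer"))
  if (!length(audio$samples)) stop("empty audio")
  fs <- audio$sample_rate
  if (fs < 4 * params$fmax)
    stop("sample_rate too low for the requested fmax")
  frame_n <- round(params$frame_length_s * fs)
  hop_n <- max(1L, round(params$hop_s * fs))
  lag_min <- max(2L, floor(fs / params$fmax))
  lag_max <- ceiling(fs / params$fmin)
  if (lag_max >= frame_n)
    stop("frame too short for fmin at this sample rate")
  starts <- seq(1L, length(audio$samples) - frame_n + 1L, by = hop_n)
  if (!length(starts)) stop("audio shorter than one analysis frame")
  nfft <- stats::nextn(2L * frame_n, 2)
  times <- f0 <- numeric(length(starts))
  for (j in seq_along(starts)) {
    x <- audio$samples[starts[j] + 0:(frame_n - 1L)]
    times[j] <- (starts[j] - 1L + frame_n / 2) / fs
    rms <- sqrt(mean(x ^ 2))
    if (rms < params$silence_rms) next
    x <- x - mean(x)
    spec <- stats::fft(c(x, numeric(nfft - frame_n)))
    ac <- Re(stats::fft(spec * Conj(spec), inverse = TRUE))[1:(lag_max + 1L)]
    if (ac[1] <= 0) next
    ac <- ac / ac[1]
    band <- (lag_min + 1L):(lag_max + 1L)       # ac[k+1] is lag k
    i <- band[which.max(ac[band])]
    if (ac[i] < params$voicing_threshold) next
    lag <- (i - 1L) + parabolic_offset(ac, i)
    cand <- fs / lag
    if (cand >= params$fmin && cand <= params$fmax) f0[j] <- cand
  }
  f0_contour(times, f0)
}

#' Signed final-word glide measurement
#'
#' The signed glide size in Hz over the final word: the OLS slope of F0 on
#' time across voiced frames inside the final-word interval, multiplied by
#' the interval duration. Regression-based measurement is robust to single
#' mistracked frames; for a linear glide it returns the end-minus-start F0
#' difference. The sign carries the statement/question classification:
#' negative glides are terminal falls, positive glides terminal rises.
#'
#' @param contour An [f0_contour]; its `final_word_interval` is used unless
#'   `interval` is supplied.
#' @param interval Optional `(start, end)` seconds overriding the contour's
#'   annotation.
#' @param min_voiced_frames Minimum voiced frames required (default 3).
#' @param edge_trim_s Frames closer than this to either interval edge are
#'   dropped. The default (0.03 s) covers half the default analysis frame
#'   plus a guard band, so no retained frame's window spans an interval
#'   boundary or an amplitude onset/offset ramp, both of which bias the
#'   autocorrelation peak.
#' @param epsilon Dead zone in Hz below which the glide is `"ambiguous"`.
#' @return A list of class `glide_measurement` with `glide_hz`, `interval`,
#'   `n_voiced_frames`, `label` (`"statement"`, `"question"` or
#'   `"ambiguous"`).
#' @export
measure_final_glide <- function(contour, interval = NULL,
                                min_voiced_frames = 3,
                                edge_trim_s = 0.03, epsilon = 1) {
  stopifnot(inherits(contour, "f0_contour"))
  if (is.null(interval)) interval <- contour$final_word_interval
  if (is.null(interval)) stop("no final-word interval available")
  sel <- contour$times >= interval[1] + edge_trim_s &
         contour$times <= interval[2] - edge_trim_s &
         !is.na(contour$f0) & contour$f0 > 0
  n_voiced <- sum(sel)
  if (n_voiced < min_voiced_frames) {
    return(structure(list(glide_hz = NA_real_, interval = interval,
                          n_voiced_frames = n_voiced, label = "ambiguous"),
                     class = "glide_measurement"))
  }
  slope <- stats::coef(stats::lm(contour$f0[sel] ~ contour$times[sel]))[2]
  glide <- unname(slope) * diff(interval)
  structure(list(glide_hz = glide, interval = interval,
                 n_voiced_frames = n_voiced,
                 label = classify_sentence_type_hz(glide, epsilon)),
            class = "glide_measurement")
}

classify_sentence_type_hz <- function(glide_hz, epsilon = 1) {
  if (is.na(glide_hz) || abs(glide_hz) < epsilon) "ambiguous"
  else if (glide_hz > 0) "question"
  else "statement"
}

#' Classify a glide measurement as statement or question
#'
#' Sign rule with a dead zone: glides above `+epsilon` Hz are questions
#' (terminal rises), below `-epsilon` statements (terminal falls), anything
#' in between ambiguous.
#'
#' @param g A `glide_measurement` (or a bare signed glide in Hz).
#' @param epsilon Dead-zone half-width in Hz.
#' @return `"statement"`, `"question"`, or `"ambiguous"`.
#' @export
classify_sentence_type <- function(g, epsilon = 1) {
  glide <- if (inherits(g, "glide_measurement")) g$glide_hz else g
  classify_sentence_type_hz(glide, epsilon)
}

#' Score an imitation against its model utterance
#'
#' An imitation is correct only when its measured glide shares the sign of
#' the model's final glide — statements imitated with final falls, questions
#' with final rises; magnitude is irrelevant. Ambiguous measurements score
#' incorrect and are flagged.
#'
#' @param model An [utterance_spec] with nonzero final glide.
#' @param imitation A `glide_measurement`.
#' @return A list with `correct` (logical), `flagged_ambiguous` (logical),
#'   `model_sign`, `imitation_sign`.
#' @export
score_imitation <- function(model, imitation) {
  stopifnot(inherits(model, "utterance_spec"),
            inherits(imitation, "glide_measurement"))
  if (model$final_glide_hz == 0) stop("model glide is zero: ambiguous model")
  ambiguous <- imitation$label == "ambiguous"
  imit_sign <- if (ambiguous) 0 else sign(imitation$glide_hz)
  list(correct = !ambiguous && imit_sign == sign(model$final_glide_hz),
       flagged_ambiguous = ambiguous,
       model_sign = sign(model$final_glide_hz),
       imitation_sign = imit_sign)
}
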