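#' Audio buffer
#'
#' A mono sample sequence with its sample rate. Samples must lie in
#' \[-1, 1\].
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param sample_rate Sample rate in Hz.
#' @return An object of class `audio_buffer`.
#' @export
audio_buffer <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (length(samples) && max(abs(samples)) > 1 + 1e-9)
    stop("samples must lie in [-1, 1]")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

# Additive synthesis of one voiced span with phase-continuous components.
# f0_fun gives F0 in Hz at each sample time; `harmonics` are multiples of F0
# with relative amplitudes `amps`. A raised-cosine ramp of `ramp_s` shapes
# onset and offset.
synth_span <- function(t, f0, sample_rate, harmonics, amps, ramp_s = 0.02) {
  phase <- 2 * pi * cumsum(f0) / sample_rate
  x <- numeric(length(t))
  for (i in seq_along(harmonics))
    x <- x + amps[i] * sin(harmonics[i] * phase)
  n_ramp <- min(round(ramp_s * sample_rate), floor(length(t) / 2))
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[length(x) - n_ramp + seq_len(n_ramp)] <-
      x[length(x) - n_ramp + seq_len(n_ramp)] * rev(ramp)
  }
  x
}

render_additive <- function(contour, sample_rate, harmonics, amps,
                            peak = 0.9) {
  stopifnot(inherits(contour, "f0_contour"))
  voiced <- !is.na(contour$f0) & contour$f0 > 0
  if (!any(voiced)) stop("contour has no voiced frames")
  fmax <- max(contour$f0[voiced])
  if (max(harmonics) * fmax >= sample_rate / 2)
    stop(sprintf(
      "Nyquist violation: component at %.0f Hz >= sample_rate/2 = %.0f Hz",
      max(harmonics) * fmax, sample_rate / 2))
  intervals <- contour$syllable_intervals
  if (is.null(intervals))
    intervals <- matrix(range(contour$times), ncol = 2)
  total <- max(contour$times[length(contour$times)], max(intervals[, 2]))
  n <- ceiling(total * sample_rate) + 1L
  samples <- numeric(n)
  tgrid <- (seq_len(n) - 1) / sample_rate
  for (k in seq_len(nrow(intervals))) {
    idx <- which(tgrid >= intervals[k, 1] & tgrid < intervals[k, 2])
    if (!length(idx)) next
    f0 <- stats::approx(contour$times, contour$f0, xout = tgrid[idx],
                        rule = 2)$y
    f0[is.na(f0) | f0 <= 0] <- 0
    samples[idx] <- synth_span(tgrid[idx], f0, sample_rate, harmonics, amps)
  }
  if (max(abs(samples)) > 0)
    samples <- samples * (peak / max(abs(samples)))
  audio_buffer(samples, sample_rate)
}

#' Render a speech-proxy waveform from an F0 contour
#'
#' Additive synthesis with harmonics 1..15 at relative amplitudes 1/n and a
#' per-syllable raised-cosine onset/offset envelope, phase-continuous within
#' each syllable. The proxy is a stand-in waveform whose only meaningful
#' property is its F0 trajectory; regions outside the syllable intervals are
#' silent.
#'
#' @param contour An [f0_contour] with at least one voiced frame.
#' @param sample_rate Sample rate in Hz (default 22050).
#' @param peak Peak amplitude of the rendered waveform.
#' @return An [audio_buffer].
#' @export
render_speech_proxy <- function(contour, sample_rate = 22050, peak = 0.9) {
  h <- 1:15
  render_additive(contour, sample_rate, h, 1 / h, peak)
}

#' Render the musical analogue of an F0 contour
#'
#' One discrete gliding tone per syllable interval, built from the
#' fundamental frequency and its seven odd harmonics (components at
#' F0 x \{1, 3, 5, 7, 9, 11, 13, 15\}; exactly 8 spectral components, no
#' even-harmonic energy). This renders a sentence's pitch and timing as
#' music-like tones with the verbal content removed.
#'
#' @inheritParams render_speech_proxy
#' @return An [audio_buffer].
#' @export
render_musical_analogue <- function(contour, sample_rate = 22050,
                                    peak = 0.9) {
  h <- seq(1, 15, by = 2)
  render_additive(contour, sample_rate, h, 1 / h, peak)
}

#' Normalize peak amplitude against a reference
#'
#' Rescales `audio` so its peak absolute amplitude equals that of
#' `reference`, as when musical analogues are matched in peak amplitude to
#' the sentences they were derived from. Scaling is linear, so the spectral
#' shape is untouched.
#'
#' @param audio [audio_buffer] to rescale.
#' @param reference [audio_buffer] providing the target peak; must be
#'   non-silent.
#' @return An [audio_buffer] with the reference's peak amplitude.
#' @export
normalize_peak <- function(audio, reference) {
  stopifnot(inherits(audio, "audio_buffer"),
            inherits(reference, "audio_buffer"))
  ref_peak <- max(abs(reference$samples))
  if (ref_peak == 0) stop("silent reference")
  in_peak <- max(abs(audio$samples))
  if (in_peak == 0) stop("cannot normalize silent audio")
  audio_buffer(audio$samples * (ref_peak / in_peak), audio$sample_rate)
}
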