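# Minimal RIFF/WAVE codec (mono/stereo PCM16 and IEEE float32), written
# against the canonical WAVE format description. Only what the package
# needs: no compressed formats, no streaming.

#' Write an audio buffer to a WAV file
#'
#' @param audio An [audio_buffer].
#' @param path Output file path.
#' @param format `"pcm16"` (16-bit integer, default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(audio, "audio_buffer"))
  format <- match.arg(format)
  fs <- as.integer(round(audio$sample_rate))
  n <- length(audio$samples)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  audio_fmt <- if (format == "pcm16") 1L else 3L   # PCM vs IEEE float
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(pmin(audio$samples, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(audio$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into an audio buffer
#'
#' Reads mono or multi-channel PCM16 / float32 WAV; multi-channel input is
#' averaged down to mono.
#'
#' @param path Path to a WAV file.
#' @return An [audio_buffer].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  audio_fmt <- NULL; n_chan <- NULL; fs <- NULL; bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_fmt <- readBin(con, "integer", size = 2, endian = "little")
      n_chan <- readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", n = extra))
    } else if (identical(id, "data")) {
      if (is.null(audio_fmt)) stop("malformed WAV: data before fmt chunk")
      if (audio_fmt == 1L && bits == 16L) {
        raw_s <- readBin(con, "integer", n = size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
        samples <- raw_s / 32767
      } else if (audio_fmt == 3L && bits == 32L) {
        samples <- readBin(con, "double", n = size %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                     audio_fmt, bits))
      }
    } else {
      invisible(readBin(con, "raw", n = size))
    }
    if (!is.null(samples) && !is.null(fs)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (n_chan > 1L)
    samples <- colMeans(matrix(samples, nrow = n_chan))
  audio_buffer(pmax(pmin(samples, 1), -1), fs)
}
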