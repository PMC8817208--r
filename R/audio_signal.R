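# AudioSignal container plus WAV input/output and resampling.
#
# WAV reading/writing is implemented directly over the RIFF chunk layout
# (PCM 16-bit and IEEE float 32-bit, the formats smartphone capture backends
# emit); stereo input is downmixed by channel averaging with a warning.

#' Construct an audio signal
#'
#' A sampled mono waveform: dimensionless amplitudes with nominal range
#' \eqn{[-1, 1]} and a fixed sampling rate in Hz.
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number")
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("audio samples must all be finite")
  }
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' Duration of an audio signal in seconds
#' @param signal An [audio_signal()].
#' @return Duration in seconds.
#' @export
audio_duration <- function(signal) length(signal$samples) / signal$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %.3f s at %g Hz (%d samples)>\n",
              audio_duration(x), x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Read a WAV file
#'
#' Supports PCM 8/16/32-bit integer and IEEE float 32/64-bit mono or stereo
#' files; stereo is downmixed to mono by averaging channels (with a warning).
#'
#' @param path Path to a RIFF/WAVE file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "RIFF")) {
    stop("not a RIFF/WAV file: ", path)
  }
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(con, "integer", 1L, 2L, signed = FALSE,
                             endian = "little"),
        sample_rate = readBin(con, "integer", 1L, 4L, endian = "little")
      )
      readBin(con, "integer", 1L, 4L, endian = "little") # byte rate
      readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little")
      fmt$bits <- readBin(con, "integer", 1L, 2L, signed = FALSE,
                          endian = "little")
      extra <- size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L) # chunks are word-aligned
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path)
  }
  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; the subformat of interest mirrors 1 or 3
  fmt_code <- fmt$audio_format
  n_bytes <- fmt$bits %/% 8L
  n_samp <- length(data_raw) %/% n_bytes
  x <- if (fmt_code %in% c(1L, 65534L) && fmt$bits == 16L) {
    readBin(data_raw, "integer", n_samp, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt_code %in% c(1L, 65534L) && fmt$bits == 32L) {
    readBin(data_raw, "integer", n_samp, 4L, endian = "little") / 2147483648
  } else if (fmt_code %in% c(1L, 65534L) && fmt$bits == 8L) {
    (readBin(data_raw, "integer", n_samp, 1L, signed = FALSE) - 128) / 128
  } else if (fmt_code == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", n_samp, 4L, endian = "little")
  } else if (fmt_code == 3L && fmt$bits == 64L) {
    readBin(data_raw, "numeric", n_samp, 8L, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit): %s",
                 fmt_code, fmt$bits, path))
  }
  if (fmt$n_channels > 1L) {
    warning("multichannel WAV downmixed to mono by channel averaging: ", path)
    n_frames <- length(x) %/% fmt$n_channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$n_channels)],
                         nrow = fmt$n_channels))
  }
  if (any(!is.finite(x))) stop("non-finite samples in WAV: ", path)
  audio_signal(x, fmt$sample_rate)
}

#' Write an audio signal to a 16-bit PCM WAV file
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  s <- pmax(-1, pmin(1, signal$samples))
  pcm <- as.integer(round(s * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")  # PCM
  writeBin(1L, con, size = 2L, endian = "little")  # mono
  fs <- as.integer(round(signal$sample_rate))
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Resample an audio signal
#'
#' Polyphase resampling (via \pkg{signal}) to a fixed analysis rate; all
#' marker extraction runs at 16 kHz so that results are independent of the
#' capture device's native rate.
#'
#' @param signal An [audio_signal()].
#' @param rate Target sampling rate in Hz.
#' @return An [audio_signal()] at `rate`.
#' @export
resample_audio <- function(signal, rate = 16000) {
  stopifnot(inherits(signal, "audio_signal"))
  if (signal$sample_rate == rate) return(signal)
  g <- gcd_int(round(rate), round(signal$sample_rate))
  p <- round(rate) / g
  q <- round(signal$sample_rate) / g
  y <- signal::resample(signal$samples, p, q)
  audio_signal(as.numeric(y), rate)
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
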