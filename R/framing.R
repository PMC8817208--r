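# Short-time framing of audio signals and the FrameTrack carrier used by all
# framewise analyses (pitch, voicing, energy).

#' Slice a signal into fixed-length analysis frames
#'
#' Frames of `frame_len` seconds are taken every `hop` seconds; a final
#' partial frame is discarded, so a signal of `N` samples yields
#' `floor((N - L) / H) + 1` frames (`L`, `H` in samples). A signal shorter
#' than one frame yields zero frames, not an error.
#'
#' @param signal An [audio_signal()].
#' @param frame_len Frame length in seconds (> 0).
#' @param hop Hop between frame starts in seconds (> 0).
#' @return A list of class `signal_frames`: `frames` (L x n matrix, one
#'   column per frame), `times` (frame midpoints, seconds), `starts`
#'   (1-based start sample of each frame), `frame_len` and `hop` in samples,
#'   and `sample_rate`.
#' @export
frame_signal <- function(signal, frame_len = 0.04, hop = 0.01) {
  stopifnot(inherits(signal, "audio_signal"), frame_len > 0, hop > 0)
  fs <- signal$sample_rate
  L <- max(1L, as.integer(round(frame_len * fs)))
  H <- max(1L, as.integer(round(hop * fs)))
  frames_by_samples(signal$samples, L, H, fs)
}

frames_by_samples <- function(x, L, H, fs) {
  N <- length(x)
  n <- if (N < L) 0L else as.integer((N - L) %/% H + 1L)
  starts <- if (n > 0L) (seq_len(n) - 1L) * H + 1L else integer(0)
  frames <- if (n > 0L) {
    matrix(x[outer(seq_len(L) - 1L, starts, "+")], nrow = L)
  } else {
    matrix(numeric(0), nrow = L, ncol = 0)
  }
  structure(list(frames = frames,
                 times = (starts - 1L + L / 2) / fs,
                 starts = starts,
                 frame_len = L, hop = H, sample_rate = fs),
            class = "signal_frames")
}

#' Framewise track of values over a signal
#'
#' Carrier for per-frame results: frame midpoint times, a per-frame scalar
#' (F0 in Hz, energy in dB, or a logical flag) and a voiced/speech flag.
#'
#' @param frame_times Frame midpoints in seconds, strictly increasing.
#' @param values Per-frame values (same length as `frame_times`).
#' @param voiced Logical voicing flag per frame.
#' @param ... Additional fields kept alongside (frame geometry, strengths,
#'   search band) so downstream operations can realign with the samples.
#' @return An object of class `frame_track`.
#' @export
frame_track <- function(frame_times, values, voiced = rep(FALSE, length(values)),
                        ...) {
  if (length(values) != length(frame_times)) {
    stop("`values` and `frame_times` must have equal length")
  }
  if (length(frame_times) > 1L && any(diff(frame_times) <= 0)) {
    stop("`frame_times` must be strictly increasing")
  }
  structure(c(list(frame_times = frame_times, values = values,
                   voiced = as.logical(voiced)), list(...)),
            class = "frame_track")
}

#' @export
print.frame_track <- function(x, ...) {
  cat(sprintf("<frame_track: %d frames, %d voiced/flagged>\n",
              length(x$values), sum(x$voiced, na.rm = TRUE)))
  invisible(x)
}
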