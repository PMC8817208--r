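# Fundamental-frequency tracking by window-normalized autocorrelation
# (Boersma-style): the frame autocorrelation is divided by the analysis
# window's own autocorrelation before peak picking, which removes the
# triangular tapering bias and lets the peak height be read as a
# harmonicity estimate.

acf_fft <- function(x, nfft) {
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_along(x)] / nfft
}

# Parabolic interpolation of the best local maximum of `r` (indexed by
# lag + 1) over lags [lag_min, lag_max]; returns fractional lag and height.
# For a perfectly periodic signal the peaks at 2x, 3x the true period are
# as high as the fundamental one, so candidates are ranked with a small
# per-octave cost favoring shorter lags before the winner is interpolated.
peak_candidate <- function(r, lag_min, lag_max, octave_cost = 0.05) {
  lags <- lag_min:lag_max
  y <- r[lags + 1L]
  if (!length(y) || all(!is.finite(y))) return(NULL)
  local <- which(diff(sign(diff(y))) < 0) + 1L # strict local maxima
  score <- y - octave_cost * log2(lags / lag_min)
  i <- if (length(local)) local[which.max(score[local])] else which.max(score)
  lag0 <- lags[i]
  if (i > 1L && i < length(y)) {
    ym1 <- y[i - 1L]; y0 <- y[i]; yp1 <- y[i + 1L]
    den <- ym1 - 2 * y0 + yp1
    delta <- if (den < 0) 0.5 * (ym1 - yp1) / den else 0
    delta <- max(-0.5, min(0.5, delta))
    list(lag = lag0 + delta, height = y0 - 0.25 * (ym1 - yp1) * delta)
  } else {
    list(lag = as.numeric(lag0), height = y[i])
  }
}

#' Framewise fundamental-frequency estimation
#'
#' Window-normalized autocorrelation pitch tracking: per frame, the signal is
#' mean-subtracted, Hann-windowed, its normalized autocorrelation divided by
#' the window autocorrelation, and the strongest peak inside the lag band
#' corresponding to `[f_min, f_max]` is located with parabolic interpolation.
#' A frame is voiced when the interpolated peak height reaches
#' `voicing_threshold` and its amplitude exceeds `silence_threshold` times
#' the global peak. Frame length defaults to `3 / f_min` seconds (three
#' periods of the lowest candidate), hop 10 ms.
#'
#' @param signal An [audio_signal()].
#' @param f_min,f_max F0 search band in Hz; requires
#'   `0 < f_min < f_max < sample_rate / 2`.
#' @param hop Hop in seconds.
#' @param frame_len Frame length in seconds (default `3 / f_min`).
#' @param voicing_threshold Normalized-autocorrelation voicing threshold.
#' @param silence_threshold Frame amplitude threshold, as a fraction of the
#'   signal's global peak.
#' @return A [frame_track()] with per-frame F0 (`values`, Hz; `NA` when
#'   unvoiced), `voiced` flags and autocorrelation peak `strength`.
#' @export
estimate_f0_track <- function(signal, f_min = 75, f_max = 500, hop = 0.01,
                              frame_len = NULL, voicing_threshold = 0.45,
                              silence_threshold = 0.03) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  if (!(f_min > 0 && f_min < f_max && f_max < fs / 2)) {
    stop("F0 search band [", f_min, ", ", f_max,
         "] Hz is infeasible for sample rate ", fs, " Hz")
  }
  if (is.null(frame_len)) frame_len <- 3 / f_min
  fr <- frame_signal(signal, frame_len, hop)
  L <- fr$frame_len
  nfr <- ncol(fr$frames)
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- min(L - 2L, ceiling(fs / f_min))
  if (lag_max <= lag_min + 1L) {
    stop("F0 search band too narrow for the analysis frame")
  }
  nfft <- 2^ceiling(log2(2L * L))
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  rw <- acf_fft(win, nfft)
  rw <- rw / rw[1]
  global_peak <- if (length(signal$samples)) max(abs(signal$samples)) else 0
  f0 <- rep(NA_real_, nfr)
  voiced <- logical(nfr)
  strength <- rep(NA_real_, nfr)
  keep <- seq_len(lag_max + 2L)
  for (j in seq_len(nfr)) {
    raw <- fr$frames[, j]
    if (global_peak == 0 || max(abs(raw)) < silence_threshold * global_peak) next
    a <- (raw - mean(raw)) * win
    ra <- acf_fft(a, nfft)
    if (ra[1] <= 0) next
    rn <- (ra[keep] / ra[1]) / rw[keep]
    cand <- peak_candidate(rn, lag_min, lag_max)
    if (is.null(cand)) next
    f <- fs / cand$lag
    if (f < f_min || f > f_max) next
    strength[j] <- cand$height
    if (cand$height >= voicing_threshold) {
      voiced[j] <- TRUE
      f0[j] <- f
    }
  }
  # de-spiking: un-voice isolated octave jumps (frames whose F0 deviates
  # from the local running median of voiced frames by more than ~0.4
  # octave, typically window-straddling frames at segment boundaries)
  vi <- which(voiced)
  if (length(vi) >= 5L) {
    med <- stats::runmed(f0[vi], 9L, endrule = "median")
    spike <- abs(log2(f0[vi] / med)) > 0.4
    voiced[vi[spike]] <- FALSE
    f0[vi[spike]] <- NA_real_
  }
  frame_track(fr$times, f0, voiced,
              strength = strength, starts = fr$starts,
              frame_len_samples = L, hop_samples = fr$hop,
              sample_rate = fs, f_min = f_min, f_max = f_max)
}

#' Summarize a pitch track
#'
#' Mean and population standard deviation of F0 over voiced frames only;
#' both markers are missing (reason `"unvoiced"`) when no frame is voiced.
#'
#' @param track A [frame_track()] from [estimate_f0_track()].
#' @return List with [marker_value()] elements `f0_mean` and `f0_stdev` (Hz).
#' @export
f0_summary <- function(track) {
  stopifnot(inherits(track, "frame_track"))
  v <- track$values[track$voiced]
  v <- v[is.finite(v)]
  if (!length(v)) {
    return(list(f0_mean = marker_value(missing_reason = "unvoiced"),
                f0_stdev = marker_value(missing_reason = "unvoiced")))
  }
  m <- mean(v)
  list(f0_mean = marker_value(m),
       f0_stdev = marker_value(sqrt(mean((v - m)^2))))
}
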