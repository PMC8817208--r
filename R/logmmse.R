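# Log-spectral-amplitude MMSE speech enhancement (Ephraim & Malah style),
# applied to every recording before acoustic marker extraction.

#' Log-MMSE speech enhancement
#'
#' Classical log-spectral-amplitude minimum mean-square-error estimator.
#' The noise power spectrum is initialized from the first `noise_seconds` of
#' the recording and updated during frames a spectral likelihood test deems
#' non-speech; the a-priori SNR follows the decision-directed rule with
#' smoothing `alpha`. Spectral gains are floored at `gain_floor` and capped
#' at 1, so enhancement can never amplify a band.
#'
#' @param signal An [audio_signal()].
#' @param noise_seconds Initial noise-profile window in seconds (> 0).
#' @param frame_len Analysis frame in seconds (Hann window, 50\% overlap).
#' @param alpha Decision-directed a-priori SNR smoothing constant.
#' @param gain_floor Minimum spectral gain (default -25 dB).
#' @return An enhanced [audio_signal()] with the same length and rate.
#' @export
logmmse_enhance <- function(signal, noise_seconds = 0.3, frame_len = 0.02,
                            alpha = 0.98, gain_floor = 10^(-25 / 20)) {
  stopifnot(inherits(signal, "audio_signal"), noise_seconds > 0)
  fs <- signal$sample_rate
  L <- 2L * max(1L, as.integer(round(frame_len * fs / 2)))
  H <- L %/% 2L
  N <- length(signal$samples)
  if (N < L) stop("too short to enhance")
  if (audio_duration(signal) < noise_seconds) {
    stop("signal shorter than the noise-profile window")
  }
  if (max(abs(signal$samples)) == 0) return(signal) # silence in, silence out
  # periodic Hann: unit-sum overlap-add at 50% without a synthesis window
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  x <- c(signal$samples, numeric(L))
  fr <- frames_by_samples(x, L, H, fs)
  nf <- ncol(fr$frames)
  spec <- stats::mvfft(fr$frames * win)
  pow <- Mod(spec)^2
  n_noise <- max(1L, sum(fr$starts + L - 1L <= round(noise_seconds * fs)))
  noise_mu2 <- pmax(rowMeans(pow[, seq_len(n_noise), drop = FALSE]),
                    .Machine$double.xmin)
  out <- numeric(length(x))
  xk_prev <- NULL
  vad_thresh <- 0.15
  for (j in seq_len(nf)) {
    sig2 <- pow[, j]
    gammak <- pmin(sig2 / noise_mu2, 40)
    if (is.null(xk_prev)) {
      ksi <- alpha + (1 - alpha) * pmax(gammak - 1, 0)
    } else {
      ksi <- alpha * xk_prev / noise_mu2 + (1 - alpha) * pmax(gammak - 1, 0)
      ksi <- pmax(ksi, 1e-3)
    }
    # spectral likelihood VAD drives noise-profile adaptation
    log_sigma_k <- gammak * ksi / (1 + ksi) - log(1 + ksi)
    if (mean(log_sigma_k) < vad_thresh) {
      noise_mu2 <- pmax(alpha * noise_mu2 + (1 - alpha) * sig2,
                        .Machine$double.xmin)
    }
    a <- ksi / (1 + ksi)
    vk <- pmax(a * gammak, 1e-12)
    gain <- a * exp(0.5 * pracma::expint_E1(vk))
    gain <- pmin(pmax(gain, gain_floor), 1)
    xk_prev <- (gain^2) * sig2
    out_frame <- Re(stats::fft(gain * spec[, j], inverse = TRUE)) / L
    idx <- fr$starts[j]:(fr$starts[j] + L - 1L)
    out[idx] <- out[idx] + out_frame
  }
  audio_signal(out[seq_len(N)], fs)
}
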