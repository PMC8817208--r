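# Synthetic voiced-audio generator with exact ground truth: a jittered
# glottal pulse train shaped by two fixed formant-like resonators plus
# calibrated white noise, interleaved with silence to a target voiced
# fraction. Realism is a non-goal; exact knowledge of every marker is.

#' Voice synthesis parameters
#'
#' @param f0 Fundamental frequency in Hz.
#' @param f0_end Optional end frequency for a linear F0 glide (`NULL` for a
#'   steady pitch).
#' @param f0_drift_sd Per-period Gaussian F0 perturbation SD in Hz (slow
#'   pitch variability; independent of jitter).
#' @param jitter_target Target local jitter in percent (cycle-to-cycle).
#' @param hnr_target Target harmonics-to-noise ratio in dB over voiced
#'   regions (`Inf` for no added noise).
#' @param intensity_scale Amplitude scale factor.
#' @param voiced_fraction Fraction of the recording that is voiced, in
#'   `[0, 1]`; silence is interleaved in fixed cycles.
#' @param duration Total duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed; the generator is bit-reproducible.
#' @return A list of class `voice_params`.
#' @export
voice_params <- function(f0 = 150, f0_end = NULL, f0_drift_sd = 0,
                         jitter_target = 0, hnr_target = Inf,
                         intensity_scale = 1, voiced_fraction = 1,
                         duration = 3, sample_rate = 16000, seed = 1) {
  stopifnot(duration > 0, jitter_target >= 0,
            voiced_fraction >= 0, voiced_fraction <= 1)
  if (f0 >= sample_rate / 2 || (!is.null(f0_end) && f0_end >= sample_rate / 2)) {
    stop("f0 at or above the Nyquist frequency is infeasible")
  }
  structure(as.list(environment()), class = "voice_params")
}

# second-order resonator (formant) filter
resonate <- function(x, freq, bw, fs) {
  r <- exp(-pi * bw / fs)
  a <- c(2 * r * cos(2 * pi * freq / fs), -r^2)
  as.numeric(stats::filter(x, a, method = "recursive"))
}

#' Synthesize voiced audio with known ground truth
#'
#' Builds a glottal pulse train at the requested pitch with per-period
#' multiplicative perturbations rescaled so the realized local jitter of
#' the true pulse-time sequence equals `jitter_target`, shapes it with two
#' fixed second-order resonators (500 Hz and 1500 Hz), and adds white noise
#' scaled so the harmonic-to-noise power ratio over voiced samples equals
#' `hnr_target` exactly by construction. Voiced segments alternate with
#' silence to achieve `voiced_fraction`.
#'
#' @param params A [voice_params()].
#' @return A list: `signal` (an [audio_signal()]) and `truth` (true pulse
#'   times in seconds, voiced segment boundaries, realized jitter percent,
#'   realized HNR in dB, and all targets).
#' @export
synth_voiced_audio <- function(params) {
  stopifnot(inherits(params, "voice_params"))
  fs <- params$sample_rate
  N <- as.integer(round(params$duration * fs))
  with_seed(params$seed, {
    # voiced/silence segmentation in fixed cycles
    segs <- if (params$voiced_fraction >= 1) {
      matrix(c(0, params$duration), ncol = 2)
    } else if (params$voiced_fraction <= 0) {
      matrix(numeric(0), ncol = 2)
    } else {
      # silence leads each cycle, so recordings open with a noise-only
      # stretch the way natural captures do (and the enhancer's initial
      # noise profile window expects)
      cycle <- min(1.25, params$duration)
      on_len <- cycle * params$voiced_fraction
      starts <- seq(0, params$duration - 1e-9, by = cycle) +
        (cycle - on_len)
      starts <- starts[starts < params$duration]
      cbind(starts, pmin(starts + on_len, params$duration))
    }
    seg_periods <- list()
    seg_t0 <- numeric(0)
    if (nrow(segs)) {
      f_of_t <- function(t) {
        if (is.null(params$f0_end)) {
          params$f0
        } else {
          params$f0 + (params$f0_end - params$f0) * t / params$duration
        }
      }
      for (i in seq_len(nrow(segs))) {
        t0 <- segs[i, 1] + 0.5 / f_of_t(segs[i, 1])
        t <- t0
        p <- numeric(0)
        while (t < segs[i, 2] - 0.5 / f_of_t(t)) {
          f <- f_of_t(t) + if (params$f0_drift_sd > 0) {
            stats::rnorm(1, 0, params$f0_drift_sd)
          } else 0
          f <- max(f, 1)
          p <- c(p, 1 / f)
          t <- t + 1 / f
        }
        seg_periods[[i]] <- p
        seg_t0[i] <- t0
      }
      # calibrate cycle-to-cycle jitter on the realized period sequence;
      # consecutive-period differences are only taken within a segment
      all_p <- unlist(seg_periods)
      if (params$jitter_target > 0 && length(all_p) >= 3L) {
        lens <- lengths(seg_periods)
        idx <- rep(seq_along(seg_periods), lens)
        e <- stats::rnorm(length(all_p), 0,
                          params$jitter_target / 100 * sqrt(pi) / 2)
        pooled_jitter <- function(p) {
          d <- unlist(lapply(split(p, idx), function(v) abs(diff(v))))
          if (!length(d)) return(0)
          100 * mean(d) / mean(p)
        }
        for (it in 1:3) {
          j_now <- pooled_jitter(all_p * (1 + e))
          if (j_now > 0) e <- e * params$jitter_target / j_now
        }
        all_p <- all_p * (1 + e)
        seg_periods <- split(all_p, idx)
      }
    }
    pulse_times <- unlist(lapply(seq_along(seg_periods), function(i) {
      p <- seg_periods[[i]]
      if (!length(p)) return(numeric(0))
      seg_t0[i] + c(0, cumsum(p[-length(p)]))
    }))
    pulse_times <- pulse_times %||% numeric(0)
    periods <- unlist(seg_periods) %||% numeric(0)
    within_seg_diffs <- unlist(lapply(seg_periods,
                                      function(v) abs(diff(v))))
    # render pulses with sub-sample placement (energy split over neighbors)
    x <- numeric(N)
    if (length(pulse_times)) {
      pos <- pulse_times * fs + 1
      i0 <- floor(pos)
      frac <- pos - i0
      ok <- i0 >= 1 & i0 < N
      x[i0[ok]] <- x[i0[ok]] + (1 - frac[ok])
      x[i0[ok] + 1L] <- x[i0[ok] + 1L] + frac[ok]
    }
    h <- resonate(resonate(x, 500, 100, fs), 1500, 150, fs)
    peak <- max(abs(h), 0)
    if (peak > 0) h <- h * (0.3 * params$intensity_scale / peak)
    voiced_mask <- logical(N)
    if (nrow(segs)) {
      for (i in seq_len(nrow(segs))) {
        a <- max(1L, as.integer(floor(segs[i, 1] * fs)) + 1L)
        b <- min(N, as.integer(ceiling(segs[i, 2] * fs)))
        if (b >= a) voiced_mask[a:b] <- TRUE
      }
    }
    realized_hnr <- Inf
    y <- h
    if (is.finite(params$hnr_target) && any(voiced_mask)) {
      ph <- mean(h[voiced_mask]^2)
      if (ph > 0) {
        noise <- stats::rnorm(N)
        pn_target <- ph / 10^(params$hnr_target / 10)
        noise <- noise * sqrt(pn_target / mean(noise[voiced_mask]^2))
        y <- h + noise
        realized_hnr <- 10 * log10(ph / mean(noise[voiced_mask]^2))
      }
    }
    peak_y <- max(abs(y), 0)
    if (peak_y > 0.99) { # headroom guard; pure rescale preserves HNR
      y <- y * (0.99 / peak_y)
    }
    realized_jitter <- if (length(within_seg_diffs)) {
      100 * mean(within_seg_diffs) / mean(periods)
    } else {
      NA_real_
    }
    list(signal = audio_signal(y, fs),
         truth = list(pulse_times = pulse_times,
                      periods = periods,
                      voiced_segments = segs,
                      voiced_fraction = params$voiced_fraction,
                      f0 = params$f0, f0_end = params$f0_end,
                      jitter_target = params$jitter_target,
                      realized_jitter = realized_jitter,
                      hnr_target = params$hnr_target,
                      realized_hnr_db = realized_hnr,
                      intensity_scale = params$intensity_scale,
                      seed = params$seed))
  })
}
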