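# Glottal-period extraction by guided peak picking, and Praat-convention
# local jitter.

# Fractional-sample refinement of a peak position by parabolic interpolation.
refine_peak <- function(x, p) {
  if (p <= 1L || p >= length(x)) return(as.numeric(p))
  ym1 <- x[p - 1L]; y0 <- x[p]; yp1 <- x[p + 1L]
  den <- ym1 - 2 * y0 + yp1
  if (den >= 0) return(as.numeric(p))
  p + max(-0.5, min(0.5, 0.5 * (ym1 - yp1) / den))
}

#' Extract glottal cycle durations from voiced regions
#'
#' Within each contiguous voiced region of the pitch track, cycle marks are
#' placed by waveform matching: starting from the strongest peak of the
#' first cycle, each next mark is found by maximizing the normalized
#' cross-correlation between a one-period template around the current mark
#' and the waveform 0.75-1.4 local-F0 periods ahead, with parabolic
#' sub-sample refinement of the correlation peak. Matching a cycle against
#' the previous cycle's actual shape cancels the systematic peak shifts
#' that formant ringing causes. Consecutive mark spacings give the period
#' sequence; periods outside `[1/f_max, 1/f_min]` are discarded. No voiced
#' region yields an empty sequence, not an error.
#'
#' @param signal The [audio_signal()] the track was computed from.
#' @param track A [frame_track()] from [estimate_f0_track()] on `signal`.
#' @return Numeric vector of periods in seconds.
#' @export
extract_periods <- function(signal, track) {
  stopifnot(inherits(signal, "audio_signal"), inherits(track, "frame_track"))
  fs <- signal$sample_rate
  x <- signal$samples
  if (abs(min(x)) > abs(max(x))) x <- -x # peak polarity convention
  voiced <- track$voiced
  if (!any(voiced)) return(numeric(0))
  L <- track$frame_len_samples
  periods <- numeric(0)
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts_run <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    j1 <- starts_run[k]; j2 <- ends[k]
    s0 <- track$starts[j1]
    s1 <- min(track$starts[j2] + L - 1L, length(x))
    f_reg <- stats::median(track$values[j1:j2], na.rm = TRUE)
    if (!is.finite(f_reg)) next
    P_reg <- fs / f_reg
    P0 <- P_reg
    w_end <- min(s0 + ceiling(1.25 * P0), s1)
    if (w_end - s0 < 3) next
    p <- s0 - 1L + which.max(x[s0:w_end]) # integer anchor of first cycle
    t_cur <- as.numeric(p)
    times <- t_cur
    repeat {
      # step by the recent measured cycle length once available, anchored
      # to the region's median F0 so the stepping can never lock onto a
      # sub- or super-harmonic of the true cycle
      n_t <- length(times)
      P <- if (n_t >= 3L) {
        stats::median(diff(times[max(1L, n_t - 5L):n_t]))
      } else {
        P_reg
      }
      if (P < 0.7 * P_reg || P > 1.45 * P_reg) P <- P_reg
      half <- max(3L, as.integer(floor(0.45 * P)))
      c0 <- as.integer(round(t_cur))
      s_lo <- as.integer(floor(0.75 * P))
      s_hi <- as.integer(ceiling(1.4 * P))
      if (c0 - half < 1L || c0 + s_hi + half > s1) break
      tmpl <- x[(c0 - half):(c0 + half)]
      e_t <- sum(tmpl^2)
      if (e_t == 0) break
      shifts <- s_lo:s_hi
      cc <- vapply(shifts, function(s) {
        seg <- x[(c0 + s - half):(c0 + s + half)]
        e_s <- sum(seg^2)
        if (e_s == 0) return(0)
        sum(tmpl * seg) / sqrt(e_t * e_s)
      }, 0)
      i <- which.max(cc)
      s_ref <- shifts[i]
      if (i > 1L && i < length(cc)) { # parabolic refinement of the cc peak
        den <- cc[i - 1L] - 2 * cc[i] + cc[i + 1L]
        if (den < 0) {
          s_ref <- s_ref +
            max(-0.5, min(0.5, 0.5 * (cc[i - 1L] - cc[i + 1L]) / den))
        }
      }
      t_cur <- t_cur + s_ref
      times <- c(times, t_cur)
    }
    if (length(times) >= 2L) periods <- c(periods, diff(times) / fs)
  }
  periods[periods >= 1 / track$f_max & periods <= 1 / track$f_min]
}

#' Local jitter (percent)
#'
#' Cycle-to-cycle irregularity of the glottal period sequence, in the Praat
#' "local jitter" convention: the mean absolute difference between
#' consecutive periods divided by the mean period, times 100.
#'
#' @param periods Numeric vector of consecutive periods in seconds.
#' @return A [marker_value()] in percent; missing (reason
#'   `"too few periods"`) when fewer than two periods are available.
#' @export
jitter_local <- function(periods) {
  periods <- as.numeric(periods)
  if (length(periods) < 2L) {
    return(marker_value(missing_reason = "too few periods"))
  }
  marker_value(100 * mean(abs(diff(periods))) / mean(periods))
}
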