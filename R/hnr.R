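# Harmonics-to-noise ratio from the normalized autocorrelation peak.

#' Harmonics-to-noise ratio in dB
#'
#' Per voiced frame the height `r` of the window-normalized autocorrelation
#' peak at the F0 lag estimates the fraction of frame power that is
#' periodic, so `10 * log10(r / (1 - r))` is the frame's harmonics-to-noise
#' ratio; the marker is the mean over voiced frames. `r` is clamped to
#' (0, 1) before the log-ratio, bounding the per-frame value at about
#' 70 dB. Missing (reason `"unvoiced"`) when no frame is voiced.
#'
#' @param signal The [audio_signal()] the track was computed from (used for
#'   consistency validation).
#' @param track A [frame_track()] from [estimate_f0_track()] on `signal`,
#'   which carries the per-frame peak strengths.
#' @return A [marker_value()] in dB.
#' @export
hnr_db <- function(signal, track) {
  stopifnot(inherits(signal, "audio_signal"), inherits(track, "frame_track"))
  if (!is.null(track$sample_rate) &&
      track$sample_rate != signal$sample_rate) {
    stop("track was not computed from this signal (sample rate mismatch)")
  }
  r <- track$strength[track$voiced]
  r <- r[is.finite(r)]
  if (!length(r)) return(marker_value(missing_reason = "unvoiced"))
  r <- pmax(1e-7, pmin(1 - 1e-7, r))
  marker_value(mean(10 * log10(r / (1 - r))))
}
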