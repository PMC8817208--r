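# Vocal intensity, energy-based speech detection, and speech prevalence.

#' Vocal intensity in dB
#'
#' Energy-weighted mean of framewise `20 * log10(RMS / ref)` with the
#' Praat-style reference `ref = 2e-5` amplitude units, computed over speech
#' frames only. The scale is uncalibrated (no microphone reference), so all
#' uses are relative. When `flags` is `NULL`, speech frames are those whose
#' peak amplitude exceeds `silence_threshold` times the signal's global
#' peak; the pipeline passes the flags from [detect_speech_frames()].
#'
#' @param signal An [audio_signal()].
#' @param flags Optional logical vector of speech flags, one per analysis
#'   frame (e.g. `values` of the track from [detect_speech_frames()]).
#' @param frame_len,hop Frame geometry in seconds.
#' @param ref Reference amplitude (2e-5).
#' @param silence_threshold Fallback speech test when `flags` is `NULL`.
#' @return A [marker_value()] in dB; missing (reason `"silent"`) for digital
#'   silence or when no speech frame exists.
#' @export
intensity_db <- function(signal, flags = NULL, frame_len = 0.04, hop = 0.01,
                         ref = 2e-5, silence_threshold = 0.03) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!length(signal$samples)) stop("empty signal")
  if (max(abs(signal$samples)) == 0) {
    return(marker_value(missing_reason = "silent"))
  }
  fr <- frame_signal(signal, frame_len, hop)
  if (ncol(fr$frames) == 0L) {
    return(marker_value(missing_reason = "too short"))
  }
  rms <- sqrt(colMeans(fr$frames^2))
  speech <- if (is.null(flags)) {
    peaks <- apply(abs(fr$frames), 2, max)
    peaks > silence_threshold * max(abs(signal$samples))
  } else {
    if (length(flags) != ncol(fr$frames)) {
      stop("`flags` length does not match the frame count")
    }
    as.logical(flags)
  }
  speech <- speech & rms > 0
  if (!any(speech)) return(marker_value(missing_reason = "silent"))
  w <- rms[speech]^2
  lvl <- 20 * log10(rms[speech] / ref)
  marker_value(sum(w * lvl) / sum(w))
}

#' Detect speech frames
#'
#' A frame is speech when it is voiced, or when its energy exceeds the
#' estimated noise floor (the `floor_quantile` quantile of framewise energy
#' in dB) by `margin_db`. The energy branch catches unvoiced speech
#' (fricatives); the voicing branch keeps quiet voiced speech.
#'
#' @param signal The [audio_signal()] the track was computed from.
#' @param track A [frame_track()] from [estimate_f0_track()] on `signal`.
#' @param margin_db Margin above the noise floor in dB.
#' @param floor_quantile Quantile of frame energies used as the noise floor.
#' @return A logical-valued [frame_track()] aligned with `track`.
#' @export
detect_speech_frames <- function(signal, track, margin_db = 9,
                                 floor_quantile = 0.10) {
  stopifnot(inherits(signal, "audio_signal"), inherits(track, "frame_track"))
  fr <- frames_by_samples(signal$samples, track$frame_len_samples,
                          track$hop_samples, signal$sample_rate)
  if (ncol(fr$frames) != length(track$values)) {
    stop("track does not align with this signal")
  }
  e <- colSums(fr$frames^2)
  edb <- ifelse(e > 0, 10 * log10(e), -Inf)
  speech <- track$voiced
  fin <- is.finite(edb)
  if (any(fin)) {
    noise_floor <- stats::quantile(edb[fin], floor_quantile, names = FALSE)
    speech <- speech | (edb > noise_floor + margin_db)
  }
  frame_track(track$frame_times, speech, voiced = speech,
              starts = track$starts,
              frame_len_samples = track$frame_len_samples,
              hop_samples = track$hop_samples,
              sample_rate = track$sample_rate)
}

#' Speech prevalence in percent
#'
#' Percentage of analysis frames flagged as speech rather than silence.
#'
#' @param flags A logical-valued [frame_track()] from
#'   [detect_speech_frames()], or a plain logical vector.
#' @return A [marker_value()] in percent of frames; missing (reason
#'   `"no frames"`) when there are zero frames.
#' @export
speech_prevalence <- function(flags) {
  v <- if (inherits(flags, "frame_track")) flags$values else flags
  v <- as.logical(v)
  if (!length(v)) return(marker_value(missing_reason = "no frames"))
  marker_value(100 * mean(v, na.rm = TRUE))
}
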