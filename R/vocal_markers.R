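# Orchestration of the six vocal acoustic markers for one recording.

#' Configuration for vocal marker extraction
#'
#' @param f0_min,f0_max F0 search band in Hz.
#' @param enhance Apply log-MMSE speech enhancement before analysis.
#' @param noise_seconds Initial noise-profile window for the enhancer.
#' @param resample_to Fixed analysis rate in Hz; recordings at any other
#'   rate are resampled first so markers do not depend on the capture rate.
#' @param voicing_threshold,silence_threshold Pitch-tracker thresholds.
#' @param hop Analysis hop in seconds.
#' @return A named list of class `vocal_config`.
#' @export
vocal_config <- function(f0_min = 75, f0_max = 500, enhance = TRUE,
                         noise_seconds = 0.3, resample_to = 16000,
                         voicing_threshold = 0.45, silence_threshold = 0.03,
                         hop = 0.01) {
  structure(list(f0_min = f0_min, f0_max = f0_max, enhance = enhance,
                 noise_seconds = noise_seconds, resample_to = resample_to,
                 voicing_threshold = voicing_threshold,
                 silence_threshold = silence_threshold, hop = hop),
            class = "vocal_config")
}

#' Extract the vocal acoustic marker set from one recording
#'
#' Applies log-MMSE enhancement once (unless disabled), then computes vocal
#' intensity, fundamental-frequency mean and standard deviation, local
#' jitter, harmonics-to-noise ratio and speech prevalence from the enhanced
#' signal. Fully deterministic: repeat calls on the same input are
#' identical.
#'
#' @param signal An [audio_signal()] (mono).
#' @param config A [vocal_config()].
#' @return An object of class `vocal_marker_set`: [marker_value()] fields
#'   `vocal_intensity` (dB), `f0_mean` (Hz), `f0_stdev` (Hz),
#'   `jitter_local` (percent), `hnr` (dB), `speech_prevalence` (percent),
#'   plus `n_frames` and `n_voiced_frames`.
#' @export
extract_vocal_markers <- function(signal, config = vocal_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!length(signal$samples)) stop("empty audio signal")
  if (signal$sample_rate != config$resample_to) {
    signal <- resample_audio(signal, config$resample_to)
  }
  min_len <- 3 / config$f0_min
  if (audio_duration(signal) < max(min_len, config$noise_seconds)) {
    missing_all <- marker_value(missing_reason = "too short")
    return(structure(list(vocal_intensity = missing_all,
                          f0_mean = missing_all, f0_stdev = missing_all,
                          jitter_local = missing_all, hnr = missing_all,
                          speech_prevalence = missing_all,
                          n_frames = 0L, n_voiced_frames = 0L,
                          config = config),
                     class = "vocal_marker_set"))
  }
  if (config$enhance && max(abs(signal$samples)) > 0) {
    signal <- logmmse_enhance(signal, noise_seconds = config$noise_seconds)
  }
  track <- estimate_f0_track(signal, f_min = config$f0_min,
                             f_max = config$f0_max, hop = config$hop,
                             voicing_threshold = config$voicing_threshold,
                             silence_threshold = config$silence_threshold)
  f0 <- f0_summary(track)
  periods <- extract_periods(signal, track)
  speech <- detect_speech_frames(signal, track)
  structure(list(
    vocal_intensity = intensity_db(signal, flags = speech$values,
                                   frame_len = track$frame_len_samples /
                                     signal$sample_rate,
                                   hop = config$hop),
    f0_mean = f0$f0_mean,
    f0_stdev = f0$f0_stdev,
    jitter_local = jitter_local(periods),
    hnr = hnr_db(signal, track),
    speech_prevalence = speech_prevalence(speech),
    n_frames = length(track$values),
    n_voiced_frames = sum(track$voiced),
    config = config
  ), class = "vocal_marker_set")
}

VOCAL_MARKERS <- c("vocal_intensity", "f0_mean", "f0_stdev",
                   "jitter_local", "hnr", "speech_prevalence")

#' @export
print.vocal_marker_set <- function(x, ...) {
  cat("<vocal_marker_set>\n")
  for (m in VOCAL_MARKERS) {
    v <- x[[m]]
    cat(sprintf("  %-18s %s\n", m,
                if (is_missing_marker(v)) {
                  paste0("missing (", v$missing_reason, ")")
                } else {
                  format(v$value, digits = 5)
                }))
  }
  invisible(x)
}

#' Tidy one marker set into long rows
#' @param x A `vocal_marker_set`.
#' @param row.names,optional Unused (S3 signature).
#' @param ... Unused.
#' @return A data.frame with columns `marker`, `value`, `missing_reason`.
#' @export
as.data.frame.vocal_marker_set <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(marker = VOCAL_MARKERS,
             value = vapply(VOCAL_MARKERS, function(m) x[[m]]$value, 0),
             missing_reason = vapply(VOCAL_MARKERS,
                                     function(m) x[[m]]$missing_reason, ""),
             row.names = NULL)
}
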