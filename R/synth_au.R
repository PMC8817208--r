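# Synthetic action-unit table generator with known expressivity ground
# truth and controllable confidence dropout.

#' Synthesize baseline and response AU tables
#'
#' Baseline frames have per-AU mean intensity `baseline_level` (plus small
#' Gaussian noise, truncated at zero); response frames have per-AU mean
#' `expressivity_multiplier * baseline_level`, so the expected pipeline
#' expressivity equals the multiplier. A `dropout_fraction` of frames in
#' each segment receives a detection confidence below 0.80.
#'
#' @param expressivity_multiplier Target expressivity (>= 0).
#' @param baseline_level Per-AU baseline mean intensity.
#' @param n_frames Number of response frames.
#' @param baseline_frames Number of baseline frames.
#' @param dropout_fraction Fraction of frames with low confidence, in
#'   `[0, 1)`.
#' @param noise_sd Framewise intensity noise SD.
#' @param fps Video frame rate (drives timestamps).
#' @param seed Integer seed.
#' @return A list with [au_frame_table()] elements `baseline` (timestamps
#'   starting at 0) and `response` (timestamps continuing after the
#'   baseline segment), plus `truth` (all targets).
#' @export
synth_au_table <- function(expressivity_multiplier = 1, baseline_level = 0.5,
                           n_frames = 120, baseline_frames = 90,
                           dropout_fraction = 0, noise_sd = 0.05,
                           fps = 30, seed = 1) {
  stopifnot(expressivity_multiplier >= 0, dropout_fraction >= 0,
            dropout_fraction < 1, n_frames >= 1, baseline_frames >= 1)
  with_seed(seed, {
    make_segment <- function(n, level, t_offset, frame_offset) {
      k <- length(AU_SET)
      vals <- matrix(pmax(0, stats::rnorm(n * k, level, noise_sd)),
                     nrow = n, ncol = k)
      colnames(vals) <- au_cols()
      dropped <- stats::runif(n) < dropout_fraction
      conf <- ifelse(dropped, stats::runif(n, 0.30, 0.79),
                     stats::runif(n, 0.88, 0.99))
      df <- data.frame(frame = frame_offset + seq_len(n),
                       timestamp = t_offset + (seq_len(n) - 1) / fps,
                       confidence = conf, success = 1)
      au_frame_table(cbind(df, as.data.frame(vals)))
    }
    baseline <- make_segment(baseline_frames, baseline_level, 0, 0L)
    response <- make_segment(n_frames,
                             expressivity_multiplier * baseline_level,
                             baseline_frames / fps, baseline_frames)
    list(baseline = baseline, response = response,
         truth = list(expressivity_multiplier = expressivity_multiplier,
                      baseline_level = baseline_level,
                      dropout_fraction = dropout_fraction, seed = seed))
  })
}
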