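# Facial action-unit frame tables (OpenFace CSV dialect), confidence
# filtering, baseline normalization, and the facial expressivity composite.

#' The 17 intensity-valued action units of the OpenFace dialect
#' @export
AU_SET <- c("01", "02", "04", "05", "06", "07", "09", "10", "12",
            "14", "15", "17", "20", "23", "25", "26", "45")

au_cols <- function(aus = AU_SET) paste0("AU", aus, "_r")

#' Construct an AU frame table from a data frame
#'
#' Validates and standardizes a framewise action-unit table: one row per
#' video frame with `frame`, `timestamp` (seconds), `confidence` (fraction
#' in `[0, 1]`), `success` (0/1) and one `AU<id>_r` intensity column
#' (FACS intensity scale, >= 0) per action unit.
#'
#' @param df A data.frame in the OpenFace column dialect.
#' @param aus Character vector of AU ids expected (default [AU_SET]).
#' @return A tibble of class `au_frame_table`.
#' @export
au_frame_table <- function(df, aus = AU_SET) {
  needed <- c("frame", "timestamp", "confidence", "success", au_cols(aus))
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("missing AU column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[, needed]
  for (col in needed) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column %s at row %d", col, bad[1]))
    }
    df[[col]] <- v
  }
  if (any(df$confidence < 0 | df$confidence > 1, na.rm = TRUE)) {
    stop("confidence must lie in [0, 1] after normalization")
  }
  if (any(df[au_cols(aus)] < 0, na.rm = TRUE)) {
    stop("AU intensities must be non-negative")
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("au_frame_table", class(out))
  attr(out, "aus") <- aus
  out
}

#' @export
`[.au_frame_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- unique(c("au_frame_table", class(out)))
    attr(out, "aus") <- attr(x, "aus")
    attr(out, "fraction_dropped") <- attr(x, "fraction_dropped")
  }
  out
}

#' Read an OpenFace-dialect AU table from CSV
#'
#' Confidence stored on a 0-100 scale is normalized to a fraction on load
#' (`auto` treats any column with a maximum above 1 as percent).
#'
#' @param path CSV file path.
#' @param confidence_unit `"auto"`, `"fraction"` or `"percent"`.
#' @param aus AU ids expected (default [AU_SET]).
#' @return An [au_frame_table()].
#' @export
read_au_table <- function(path, confidence_unit = c("auto", "fraction",
                                                    "percent"),
                          aus = AU_SET) {
  confidence_unit <- match.arg(confidence_unit)
  if (!file.exists(path)) stop("AU table not found: ", path)
  df <- utils::read.csv(path, check.names = TRUE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  if (!"confidence" %in% names(df)) stop("missing AU column(s): confidence")
  conf <- suppressWarnings(as.numeric(df$confidence))
  if (confidence_unit == "percent" ||
      (confidence_unit == "auto" && any(conf > 1, na.rm = TRUE))) {
    df$confidence <- conf / 100
  }
  au_frame_table(df, aus = aus)
}

#' Filter frames by detection confidence
#'
#' Keeps frames whose face-detection confidence is at or above `threshold`
#' (the boundary is inclusive: a frame at exactly the threshold is kept).
#' Frames with `success == 0` are dropped regardless of confidence. The
#' fraction of frames dropped is recorded in the `fraction_dropped`
#' attribute.
#'
#' @param table An [au_frame_table()].
#' @param threshold Confidence threshold in `[0, 1]` (default 0.80).
#' @return The filtered [au_frame_table()]; may be empty.
#' @export
filter_confidence <- function(table, threshold = 0.80) {
  stopifnot(inherits(table, "au_frame_table"),
            threshold >= 0, threshold <= 1)
  keep <- table$confidence >= threshold & table$success > 0
  out <- table[keep, ]
  class(out) <- class(table)
  attr(out, "aus") <- attr(table, "aus")
  attr(out, "fraction_dropped") <-
    if (nrow(table)) 1 - sum(keep) / nrow(table) else 0
  out
}

#' Per-AU baseline profile
#'
#' Mean intensity of each action unit over the pre-stimulus baseline
#' segment (already confidence-filtered). Any AU whose baseline mean falls
#' below `epsilon` is floored to `epsilon` and flagged, so later division
#' is always well defined.
#'
#' @param baseline_segment A confidence-filtered [au_frame_table()] of
#'   baseline frames.
#' @param epsilon Baseline floor (default 1e-3).
#' @return A list of class `baseline_profile`: `means` (named per-AU
#'   vector), `n_frames_used`, `floored` (AU ids floored).
#' @export
baseline_profile <- function(baseline_segment, epsilon = 1e-3) {
  stopifnot(inherits(baseline_segment, "au_frame_table"))
  if (!nrow(baseline_segment)) stop("no usable baseline")
  aus <- attr(baseline_segment, "aus") %||% AU_SET
  m <- colMeans(as.matrix(baseline_segment[, au_cols(aus), drop = FALSE]))
  floored <- aus[m < epsilon]
  m[m < epsilon] <- epsilon
  structure(list(means = m, n_frames_used = nrow(baseline_segment),
                 floored = floored, aus = aus),
            class = "baseline_profile")
}

#' Baseline-normalize an AU table
#'
#' Divides every framewise AU intensity by that AU's baseline mean from the
#' same assessment timepoint.
#'
#' @param table A confidence-filtered [au_frame_table()].
#' @param baseline A [baseline_profile()] from the same assessment.
#' @return The normalized [au_frame_table()].
#' @export
normalize_aus <- function(table, baseline) {
  stopifnot(inherits(table, "au_frame_table"),
            inherits(baseline, "baseline_profile"))
  aus <- attr(table, "aus") %||% AU_SET
  miss <- setdiff(au_cols(aus), names(baseline$means))
  if (length(miss)) {
    stop("AU(s) absent from baseline profile: ", paste(miss, collapse = ", "))
  }
  for (col in au_cols(aus)) {
    table[[col]] <- table[[col]] / baseline$means[[col]]
  }
  table
}

#' Facial expressivity composite
#'
#' The grand mean of all baseline-normalized AU intensities over all
#' retained frames; the same formula is used for evoked and spontaneous
#' contexts.
#'
#' @param table A normalized [au_frame_table()].
#' @return A list of class `expressivity_result`: `facial_expressivity`
#'   (a [marker_value()]), `n_frames_used`, `fraction_dropped_low_confidence`.
#' @export
facial_expressivity <- function(table) {
  stopifnot(inherits(table, "au_frame_table"))
  aus <- attr(table, "aus") %||% AU_SET
  dropped <- attr(table, "fraction_dropped") %||% 0
  if (!nrow(table)) {
    return(structure(list(
      facial_expressivity = marker_value(missing_reason = "no confident frames"),
      n_frames_used = 0L,
      fraction_dropped_low_confidence = dropped),
      class = "expressivity_result"))
  }
  structure(list(
    facial_expressivity =
      marker_value(mean(as.matrix(table[, au_cols(aus), drop = FALSE]))),
    n_frames_used = nrow(table),
    fraction_dropped_low_confidence = dropped),
    class = "expressivity_result")
}

#' Facial expressivity from one assessment's AU table
#'
#' Convenience orchestrator used by the pipeline: splits the table into the
#' pre-stimulus baseline segment (timestamps below `baseline_end_seconds`)
#' and the response segment, confidence-filters both, computes the baseline
#' profile, normalizes the response and returns its expressivity.
#'
#' @param table An [au_frame_table()] covering the whole assessment.
#' @param baseline_end_seconds End of the pre-stimulus baseline segment.
#' @param threshold Confidence threshold (default 0.80).
#' @return An `expressivity_result` (see [facial_expressivity()]).
#' @export
expressivity_from_table <- function(table, baseline_end_seconds = 3,
                                    threshold = 0.80) {
  stopifnot(inherits(table, "au_frame_table"))
  base <- filter_confidence(table[table$timestamp < baseline_end_seconds, ],
                            threshold)
  resp <- filter_confidence(table[table$timestamp >= baseline_end_seconds, ],
                            threshold)
  if (!nrow(base)) {
    return(structure(list(
      facial_expressivity = marker_value(missing_reason = "no usable baseline"),
      n_frames_used = 0L,
      fraction_dropped_low_confidence = attr(resp, "fraction_dropped")),
      class = "expressivity_result"))
  }
  facial_expressivity(normalize_aus(resp, baseline_profile(base)))
}
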