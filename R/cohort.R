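# Cohort simulator: a latent severity variable drives both PANSS items and
# digital marker values with configurable correlation strength, emulating a
# two-visit, multi-assessment remote study design.

#' Default marker generative model for cohort simulation
#'
#' One row per digital marker: population mean `mu`, per-assessment noise
#' SD `noise_sd`, and `target_r`, the population correlation between the
#' participant-level marker and latent severity the simulator calibrates
#' its loading to. Values emulate plausible clinical scales for each
#' marker; replace `target_r` (e.g. with zeros) to simulate null cohorts.
#' @export
MARKER_MODEL_DEFAULTS <- data.frame(
  marker = c("vocal_intensity", "f0_mean", "f0_stdev", "jitter_local",
             "hnr", "speech_prevalence", "facial_expressivity"),
  mu = c(70, 170, 12, 1.5, 15, 65, 1.5),
  noise_sd = c(2, 8, 2, 0.25, 1.5, 6, 0.15),
  target_r = c(-0.3, -0.6, -0.4, 0.5, -0.6, -0.5, -0.6),
  stringsAsFactors = FALSE)

CONTEXT_MARKERS <- list(
  free_behavior = c("facial_expressivity", "vocal_intensity", "f0_mean",
                    "f0_stdev", "jitter_local", "hnr", "speech_prevalence"),
  evoked_facial = "facial_expressivity",
  evoked_vocal = c("vocal_intensity", "f0_mean", "f0_stdev", "jitter_local",
                   "hnr", "speech_prevalence"))

CONTEXT_DAYS <- list(free_behavior = c(2L, 7L, 14L),
                     evoked_facial = c(1L, 7L, 14L),
                     evoked_vocal = c(1L, 7L, 14L))

#' Cohort simulation parameters
#'
#' A one-factor model: each participant carries a latent severity
#' `z ~ N(0, 1)`; every marker's participant-level mean is
#' `mu + loading * z`, and every PANSS item discretizes
#' `item_loading * z + noise` onto 1..7 through ordinal cut points. Marker
#' loadings are derived from `target_r`, the desired population correlation
#' between the participant-level (assessment-averaged) marker and severity:
#' `loading = sign(r) * (noise_sd / sqrt(n_assessments)) * |r| / sqrt(1 - r^2)`.
#'
#' @param n_participants Number of participants (>= 3).
#' @param marker_model Data frame with columns `marker`, `mu`, `noise_sd`,
#'   `target_r` (defaults emulate plausible clinical marker scales).
#' @param item_loading PANSS item loading on severity, in (0, 1).
#' @param cutpoints Strictly increasing latent cut points mapping to scores
#'   2..7.
#' @param visit_days PANSS visit days (two visits).
#' @param n_assessments Remote assessments per participant per context.
#' @param missingness Probability an assessment marker value is missing.
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 20,
                          marker_model = MARKER_MODEL_DEFAULTS,
                          item_loading = 0.7,
                          cutpoints = stats::qnorm(c(0.35, 0.60, 0.78,
                                                     0.89, 0.955, 0.99)),
                          visit_days = c(1L, 14L),
                          n_assessments = 3L,
                          missingness = 0,
                          seed = 1) {
  stopifnot(n_participants >= 3, missingness >= 0, missingness < 1,
            all(marker_model$noise_sd >= 0),
            all(abs(marker_model$target_r) < 1))
  if (length(cutpoints) != 6L || any(diff(cutpoints) <= 0)) {
    stop("infeasible ordinal cut points (need 6 strictly increasing values)")
  }
  structure(as.list(environment()), class = "cohort_params")
}

loading_for_target_r <- function(target_r, noise_sd, n_assessments) {
  s_bar <- noise_sd / sqrt(n_assessments)
  sign(target_r) * s_bar * abs(target_r) / sqrt(1 - target_r^2)
}

#' Simulate a cohort with known ground truth
#'
#' Draws latent severities, generates per-assessment marker values and
#' two-visit PANSS item scores, and (optionally) renders the full input
#' bundle the pipeline consumes: WAV audio for vocal contexts,
#' OpenFace-dialect AU tables for facial contexts, a PANSS CSV, a YAML
#' manifest and a `ground_truth.json`. Fully reproducible for a fixed seed.
#'
#' @param params A [cohort_params()].
#' @param render `"markers"` (marker-level values only, fast) or `"files"`
#'   (render audio/AU-table files under `out_dir`).
#' @param out_dir Output directory, required when `render = "files"`.
#' @param audio_duration Rendered recording length in seconds.
#' @return A list: `marker_rows` (tidy per-assessment tibble), `panss`
#'   (list of [panss_record()]s), `truth` (severities, loadings, seed), and
#'   for rendered bundles `manifest_path`.
#' @export
simulate_cohort <- function(params, render = c("markers", "files"),
                            out_dir = NULL, audio_duration = 2.5) {
  stopifnot(inherits(params, "cohort_params"))
  render <- match.arg(render)
  if (render == "files" && is.null(out_dir)) {
    stop("`out_dir` is required when rendering files")
  }
  mm <- params$marker_model
  mm$loading <- loading_for_target_r(mm$target_r, mm$noise_sd,
                                     params$n_assessments)
  n <- params$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  with_seed(params$seed, {
    z <- stats::rnorm(n)
    rows <- list()
    for (ctx in names(CONTEXT_MARKERS)) {
      days <- CONTEXT_DAYS[[ctx]][seq_len(min(params$n_assessments,
                                              length(CONTEXT_DAYS[[ctx]])))]
      grid <- expand.grid(pid = seq_len(n), day = days)
      for (m in CONTEXT_MARKERS[[ctx]]) {
        mi <- mm[mm$marker == m, ]
        val <- mi$mu + mi$loading * z[grid$pid] +
          stats::rnorm(nrow(grid), 0, mi$noise_sd)
        missing <- stats::runif(nrow(grid)) < params$missingness
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant_id = ids[grid$pid],
          assessment_id = sprintf("%s_d%02d_%s", ids[grid$pid],
                                  grid$day, ctx),
          day = as.integer(grid$day), task_context = ctx, marker = m,
          value = ifelse(missing, NA_real_, val),
          missing_reason = ifelse(missing, "simulated dropout",
                                  NA_character_))
      }
    }
    marker_rows <- dplyr::arrange(dplyr::bind_rows(rows),
                                  .data$participant_id, .data$task_context,
                                  .data$day, .data$marker)
    # PANSS items: one-factor ordinal model, two visits
    lam <- params$item_loading
    panss <- list()
    for (v in params$visit_days) {
      for (i in seq_len(n)) {
        latent <- lam * z[i] +
          sqrt(1 - lam^2) * stats::rnorm(length(PANSS_ITEMS))
        score <- 1L + vapply(latent,
                             function(u) sum(u > params$cutpoints), 0L)
        panss[[length(panss) + 1L]] <-
          panss_record(ids[i], v, stats::setNames(score, PANSS_ITEMS))
      }
    }
    truth <- list(severity = stats::setNames(z, ids),
                  loadings = stats::setNames(mm$loading, mm$marker),
                  target_r = stats::setNames(mm$target_r, mm$marker),
                  n_assessments = params$n_assessments,
                  seed = params$seed)
    bundle <- list(marker_rows = marker_rows, panss = panss, truth = truth)
    if (render == "files") {
      bundle$manifest_path <- render_cohort_files(bundle, params, out_dir,
                                                  audio_duration)
    }
    bundle
  })
}

# Map one assessment's marker values onto voice-synthesis parameters,
# clamped to physically renderable ranges.
voice_params_from_markers <- function(vals, duration, seed) {
  get <- function(m, default) {
    v <- vals$value[vals$marker == m]
    if (length(v) && is.finite(v)) v else default
  }
  voice_params(
    f0 = min(max(get("f0_mean", 160), 90), 400),
    f0_drift_sd = min(max(get("f0_stdev", 10), 0), 40),
    jitter_target = min(max(get("jitter_local", 1), 0.05), 8),
    hnr_target = min(max(get("hnr", 15), 1), 35),
    intensity_scale = 10^((min(max(get("vocal_intensity", 70), 55), 85) -
                             70) / 20),
    voiced_fraction = min(max(get("speech_prevalence", 65) / 100, 0.1), 0.95),
    duration = duration, sample_rate = 16000, seed = seed)
}

render_cohort_files <- function(bundle, params, out_dir, audio_duration) {
  dir.create(file.path(out_dir, "audio"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "au"), showWarnings = FALSE)
  assessments <- list()
  by_aid <- split(bundle$marker_rows,
                  bundle$marker_rows$assessment_id)
  counter <- 0L
  for (aid in names(by_aid)) {
    vals <- by_aid[[aid]]
    counter <- counter + 1L
    entry <- list(participant_id = vals$participant_id[1],
                  assessment_id = aid,
                  day = as.integer(vals$day[1]),
                  task_context = vals$task_context[1])
    sub_seed <- (params$seed * 10007L + counter) %% 2147483647L
    if (entry$task_context %in% c("evoked_vocal", "free_behavior")) {
      vp <- voice_params_from_markers(vals, audio_duration, sub_seed)
      wav <- file.path("audio", paste0(aid, ".wav"))
      write_wav(synth_voiced_audio(vp)$signal, file.path(out_dir, wav))
      entry$audio <- wav
    }
    if (entry$task_context %in% c("evoked_facial", "free_behavior")) {
      fe <- vals$value[vals$marker == "facial_expressivity"]
      fe <- if (length(fe) && is.finite(fe)) min(max(fe, 0.1), 5) else 1.5
      tabs <- synth_au_table(expressivity_multiplier = fe,
                             n_frames = 90, baseline_frames = 60,
                             seed = sub_seed)
      tab <- rbind(as.data.frame(tabs$baseline),
                   as.data.frame(tabs$response))
      auf <- file.path("au", paste0(aid, ".csv"))
      utils::write.csv(tab, file.path(out_dir, auf), row.names = FALSE)
      entry$au_table <- auf
      entry$baseline_end_seconds <- 60 / 30
    }
    assessments[[length(assessments) + 1L]] <- entry
  }
  panss_df <- do.call(rbind, lapply(bundle$panss, function(r) {
    cbind(data.frame(participant_id = r$participant_id,
                     visit_day = r$visit_day),
          as.data.frame(as.list(r$items)))
  }))
  utils::write.csv(panss_df, file.path(out_dir, "panss.csv"),
                   row.names = FALSE)
  manifest <- list(
    panss_csv = "panss.csv",
    config = list(seed = params$seed, confidence_threshold = 0.8,
                  f0_min = 75, f0_max = 500),
    assessments = assessments)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  jsonlite::write_json(
    list(severity = as.list(bundle$truth$severity),
         loadings = as.list(bundle$truth$loadings),
         target_r = as.list(bundle$truth$target_r),
         seed = params$seed),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  manifest_path
}
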