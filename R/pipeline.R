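# Manifest-driven end-to-end orchestration: validate inputs, extract
# markers per assessment (failures logged and skipped), aggregate,
# score PANSS, and write correlation and reliability tables.

VALID_CONTEXTS <- c("free_behavior", "evoked_facial", "evoked_vocal")

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    root <- dirname(normalizePath(manifest))
    m <- yaml::read_yaml(manifest)
    m$.root <- root
    m
  } else {
    manifest$.root <- manifest$.root %||% "."
    manifest
  }
}

manifest_path <- function(m, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(m$.root, p)
}

#' Validate a study manifest
#'
#' Checks the manifest structure against the task-context contract: every
#' referenced file must exist, `task_context` must be one of
#' `free_behavior`, `evoked_facial`, `evoked_vocal`; evoked-vocal entries
#' need audio, evoked-facial entries need an AU table, free-behavior
#' entries may carry both. A missing PANSS file or zero valid assessments
#' is fatal for [run_pipeline()].
#'
#' @param manifest Path to a YAML manifest, or an equivalent list.
#' @return A list of class `manifest_validation`: `errors`, `warnings`,
#'   `n_valid` (count of usable assessment entries).
#' @export
validate_manifest <- function(manifest) {
  m <- read_manifest(manifest)
  errors <- character(0)
  warnings <- character(0)
  if (is.null(m$panss_csv)) {
    errors <- c(errors, "manifest declares no PANSS file")
  } else if (is.null(manifest_path(m, m$panss_csv)) ||
             !file.exists(manifest_path(m, m$panss_csv))) {
    errors <- c(errors, paste0("PANSS file not found: ", m$panss_csv))
  }
  n_valid <- 0L
  for (i in seq_along(m$assessments)) {
    a <- m$assessments[[i]]
    tag <- a$assessment_id %||% paste0("assessment #", i)
    ok <- TRUE
    if (is.null(a$participant_id)) {
      errors <- c(errors, paste0(tag, ": missing participant_id"))
      ok <- FALSE
    }
    if (is.null(a$task_context) || !a$task_context %in% VALID_CONTEXTS) {
      errors <- c(errors, paste0(tag, ": unknown task_context '",
                                 a$task_context %||% "", "'"))
      ok <- FALSE
    } else {
      if (a$task_context %in% c("evoked_vocal", "free_behavior") &&
          is.null(a$audio) && a$task_context == "evoked_vocal") {
        errors <- c(errors, paste0(tag, ": evoked_vocal entry lacks an ",
                                   "audio path"))
        ok <- FALSE
      }
      if (a$task_context %in% c("evoked_facial") && is.null(a$au_table)) {
        errors <- c(errors, paste0(tag, ": evoked_facial entry lacks an ",
                                   "AU table path"))
        ok <- FALSE
      }
      if (a$task_context == "free_behavior" && is.null(a$audio) &&
          is.null(a$au_table)) {
        errors <- c(errors, paste0(tag, ": free_behavior entry has neither ",
                                   "audio nor AU table"))
        ok <- FALSE
      }
    }
    for (f in c("audio", "au_table")) {
      if (!is.null(a[[f]]) && !file.exists(manifest_path(m, a[[f]]))) {
        errors <- c(errors, paste0(tag, ": declared ", f, " not found: ",
                                   a[[f]]))
        ok <- FALSE
      }
    }
    if (ok) n_valid <- n_valid + 1L
  }
  if (!length(m$assessments)) {
    errors <- c(errors, "manifest declares zero assessments")
  }
  structure(list(errors = errors, warnings = warnings, n_valid = n_valid),
            class = "manifest_validation")
}

#' @export
print.manifest_validation <- function(x, ...) {
  cat(sprintf("<manifest_validation: %d valid, %d error(s), %d warning(s)>\n",
              x$n_valid, length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Run the full marker pipeline from a manifest
#'
#' Extracts vocal markers (after log-MMSE enhancement) and facial
#' expressivity per assessment, aggregates to participant level, derives
#' averaged PANSS scores, and writes the output bundle under `out_dir`:
#' `markers_assessment.csv`, `profiles_participant.csv`,
#' `clinical_scores.csv`, one `correlations_<context>.csv` per task
#' context, `icc_test_retest.csv`, and `run_log.txt`. Per-assessment
#' failures are logged and skipped; the run only fails when nothing usable
#' remains. Outputs are byte-identical across re-runs with the same
#' inputs, except timestamps inside the log.
#'
#' @param manifest Path to a YAML manifest (or equivalent list).
#' @param out_dir Output directory (created if needed).
#' @param config Optional overrides: `confidence_threshold`, `f0_min`,
#'   `f0_max`, `family_spec`, `enhance`.
#' @return Invisibly, a list with the in-memory tables
#'   (`markers`, `profiles`, `clinical`, `correlations`, `icc`).
#' @export
run_pipeline <- function(manifest, out_dir, config = list()) {
  m <- read_manifest(manifest)
  val <- validate_manifest(m)
  if (length(val$errors) && val$n_valid == 0L) {
    stop("manifest has no usable assessments:\n  ",
         paste(val$errors, collapse = "\n  "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("run started %s", format(Sys.time())),
                 sprintf("dbmarkers version %s",
                         as.character(utils::packageVersion("dbmarkers"))))
  cfg <- utils::modifyList(list(confidence_threshold = 0.80,
                                f0_min = 75, f0_max = 500,
                                family_spec = "per_context_scales",
                                enhance = TRUE),
                           utils::modifyList(m$config %||% list(), config))
  log_lines <- c(log_lines, paste0("config: ", jsonlite::toJSON(
    cfg[order(names(cfg))], auto_unbox = TRUE)))
  vcfg <- vocal_config(f0_min = cfg$f0_min, f0_max = cfg$f0_max,
                       enhance = cfg$enhance)
  rows <- list()
  n_skipped <- 0L
  for (a in m$assessments) {
    tag <- a$assessment_id %||% "unnamed"
    base <- tibble::tibble(participant_id = a$participant_id %||% NA,
                           assessment_id = tag,
                           day = as.integer(a$day %||% NA),
                           task_context = a$task_context %||% NA)
    if (!is.null(a$audio) &&
        a$task_context %in% c("evoked_vocal", "free_behavior")) {
      res <- tryCatch({
        sig <- read_wav(manifest_path(m, a$audio))
        cbind(base, as.data.frame(extract_vocal_markers(sig, vcfg)))
      }, error = function(e) {
        log_lines <<- c(log_lines, sprintf("skip %s (audio): %s", tag,
                                           conditionMessage(e)))
        n_skipped <<- n_skipped + 1L
        NULL
      })
      if (!is.null(res)) {
        log_lines <- c(log_lines, sprintf("ok %s: vocal markers from %s",
                                          tag, a$audio))
        rows[[length(rows) + 1L]] <- res
      }
    }
    if (!is.null(a$au_table) &&
        a$task_context %in% c("evoked_facial", "free_behavior")) {
      res <- tryCatch({
        tab <- read_au_table(manifest_path(m, a$au_table))
        er <- expressivity_from_table(
          tab, baseline_end_seconds = a$baseline_end_seconds %||% 3,
          threshold = cfg$confidence_threshold)
        cbind(base, data.frame(
          marker = "facial_expressivity",
          value = er$facial_expressivity$value,
          missing_reason = er$facial_expressivity$missing_reason))
      }, error = function(e) {
        log_lines <<- c(log_lines, sprintf("skip %s (AU table): %s", tag,
                                           conditionMessage(e)))
        n_skipped <<- n_skipped + 1L
        NULL
      })
      if (!is.null(res)) {
        log_lines <- c(log_lines, sprintf("ok %s: expressivity from %s",
                                          tag, a$au_table))
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (!length(rows)) {
    stop("pipeline produced no markers; ", n_skipped,
         " assessment(s) skipped — see log")
  }
  markers <- dplyr::bind_rows(rows)
  profiles <- aggregate_assessments(markers)
  panss <- read_panss_csv(manifest_path(m, m$panss_csv))
  clinical <- clinical_scores_table(panss)
  correlations <- correlation_table(profiles, clinical,
                                    family_spec = cfg$family_spec)
  icc <- icc_by_week(markers)
  write_csv_out <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  write_csv_out(markers, "markers_assessment.csv")
  write_csv_out(profiles, "profiles_participant.csv")
  write_csv_out(clinical, "clinical_scores.csv")
  for (ctx in unique(correlations$task_context)) {
    write_csv_out(correlations[correlations$task_context == ctx, ],
                  paste0("correlations_", ctx, ".csv"))
  }
  write_csv_out(icc, "icc_test_retest.csv")
  log_lines <- c(log_lines,
                 sprintf("%d marker rows from %d assessments; %d skipped",
                         nrow(markers),
                         length(unique(markers$assessment_id)), n_skipped),
                 sprintf("run finished %s", format(Sys.time())))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(markers = markers, profiles = profiles,
                 clinical = clinical, correlations = correlations,
                 icc = icc, n_skipped = n_skipped))
}

# Test-retest reliability: week 1 = assessments on days 1-7, week 2 =
# days 8-14, averaged within week per participant, ICC(A,1) per
# context x marker.
icc_by_week <- function(markers) {
  markers$week <- ifelse(markers$day <= 7, "week1", "week2")
  agg <- markers |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$participant_id, .data$task_context,
                    .data$marker, .data$week) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  combos <- unique(agg[, c("task_context", "marker")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- agg[agg$task_context == combos$task_context[i] &
                 agg$marker == combos$marker[i], ]
    w1 <- sub[sub$week == "week1", ]
    w2 <- sub[sub$week == "week2", ]
    ids <- intersect(w1$participant_id, w2$participant_id)
    r <- icc_test_retest(w1$value[match(ids, w1$participant_id)],
                         w2$value[match(ids, w2$participant_id)])
    tibble::tibble(task_context = combos$task_context[i],
                   marker = combos$marker[i],
                   icc = r$icc, n = r$n, note = r$note)
  })
  dplyr::bind_rows(rows)
}
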