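# Marker aggregation, Pearson correlation tables with Benjamini-Hochberg
# adjustment, and test-retest intraclass correlation.

#' Aggregate per-assessment markers to participant level
#'
#' Arithmetic mean per participant x task context x marker over non-missing
#' assessment values; the number of contributing assessments is recorded per
#' cell. All-missing combinations yield `NA` with `n_assessments = 0`.
#'
#' @param marker_rows A data frame with columns `participant_id`,
#'   `task_context`, `marker`, `value` (`NA` when missing).
#' @return A tibble with columns `participant_id`, `task_context`,
#'   `marker`, `value`, `n_assessments`.
#' @export
aggregate_assessments <- function(marker_rows) {
  stopifnot(all(c("participant_id", "task_context", "marker", "value") %in%
                  names(marker_rows)))
  marker_rows |>
    dplyr::group_by(.data$participant_id, .data$task_context, .data$marker) |>
    dplyr::summarise(
      n_assessments = sum(!is.na(.data$value)),
      value = if (any(!is.na(.data$value))) {
        mean(.data$value, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop") |>
    dplyr::select("participant_id", "task_context", "marker",
                  "value", "n_assessments")
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation after pairwise deletion of missing values;
#' the two-sided p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Degenerate inputs (fewer than 3 complete
#' pairs, or a constant vector) return a flagged undefined result rather
#' than `NaN`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list: `r`, `p_raw`, `n`, and `note` (`NA` when defined).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(list(r = NA_real_, p_raw = NA_real_, n = n,
                note = "fewer than 3 complete pairs"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_raw = NA_real_, n = n,
                note = "constant vector"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_raw = ct$p.value, n = n, note = NA_character_)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of a family of p-values: sorted
#' ascending, `q_i = p_i * m / i`, made monotone non-decreasing from the
#' largest rank down, capped at 1, and returned in the original order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   passed through).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Marker-versus-scale correlation table
#'
#' Builds the full grid of Pearson correlations between participant-level
#' markers and clinical scale scores within each task context, plus the
#' marker-marker intercorrelations, with Benjamini-Hochberg adjustment
#' applied within the family defined by `family_spec`:
#' \describe{
#'   \item{`per_context_scales`}{(default) all marker-vs-scale cells of one
#'     task-context table form one family; marker-marker cells are reported
#'     unadjusted.}
#'   \item{`per_context_all`}{all cells of one context's table, including
#'     intercorrelations, form one family.}
#' }
#' The negative-symptom column uses the Marder negative factor; positive,
#' general and total severity use the subscale totals.
#'
#' @param profiles Participant-level marker tibble from
#'   [aggregate_assessments()].
#' @param clinical Per-participant scores from [clinical_scores_table()].
#' @param scales Named character vector mapping display scale names to
#'   columns of `clinical`.
#' @param family_spec Multiple-testing family (see above).
#' @param include_intermarker Include marker-marker cells.
#' @return A tibble with columns `task_context`, `marker`, `scale`, `r`,
#'   `p_raw`, `p_adjusted`, `n`, `note`.
#' @export
correlation_table <- function(profiles, clinical,
                              scales = c(negative_marder = "marder_negative",
                                         positive = "p_total",
                                         general = "g_total",
                                         total = "panss_total"),
                              family_spec = c("per_context_scales",
                                              "per_context_all"),
                              include_intermarker = TRUE) {
  family_spec <- match.arg(family_spec)
  stopifnot(all(c("participant_id", "task_context", "marker", "value") %in%
                  names(profiles)))
  rows <- list()
  for (ctx in sort(unique(profiles$task_context))) {
    sub <- profiles[profiles$task_context == ctx, ]
    markers <- sort(unique(sub$marker))
    wide <- dplyr::left_join(
      tidyr_pivot(sub, markers),
      clinical, by = "participant_id")
    for (m in markers) {
      for (s in names(scales)) {
        pc <- pearson_corr(wide[[m]], wide[[scales[[s]]]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          task_context = ctx, marker = m, scale = s,
          r = pc$r, p_raw = pc$p_raw, p_adjusted = NA_real_,
          n = pc$n, note = pc$note, family = "scale")
      }
    }
    if (include_intermarker && length(markers) > 1L) {
      pairs <- utils::combn(markers, 2)
      for (k in seq_len(ncol(pairs))) {
        pc <- pearson_corr(wide[[pairs[1, k]]], wide[[pairs[2, k]]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          task_context = ctx, marker = pairs[1, k], scale = pairs[2, k],
          r = pc$r, p_raw = pc$p_raw, p_adjusted = NA_real_,
          n = pc$n, note = pc$note, family = "marker")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  for (ctx in unique(out$task_context)) {
    in_family <- out$task_context == ctx &
      (out$family == "scale" | family_spec == "per_context_all")
    out$p_adjusted[in_family] <- bh_adjust(out$p_raw[in_family])
  }
  out$family <- NULL
  out
}

# participant x marker wide layout (one column per marker)
tidyr_pivot <- function(sub, markers) {
  ids <- sort(unique(sub$participant_id))
  wide <- tibble::tibble(participant_id = ids)
  for (m in markers) {
    v <- sub[sub$marker == m, ]
    wide[[m]] <- v$value[match(ids, v$participant_id)]
  }
  wide
}

#' Test-retest intraclass correlation, ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-measure intraclass
#' correlation between two measurement occasions, computed from the
#' standard ANOVA mean squares:
#' \deqn{ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n)}
#' with `n` subjects, `k = 2` occasions, rows = subjects, columns =
#' occasions.
#'
#' @param week1,week2 Paired per-participant marker values.
#' @return A list: `icc`, `n`, `k`, mean squares `ms_rows`, `ms_cols`,
#'   `ms_error`, and `note` (`NA` when defined).
#' @export
icc_test_retest <- function(week1, week2) {
  if (length(week1) != length(week2)) {
    stop("`week1` and `week2` must have equal length")
  }
  ok <- stats::complete.cases(week1, week2)
  week1 <- week1[ok]
  week2 <- week2[ok]
  n <- length(week1)
  if (n < 3L) {
    return(list(icc = NA_real_, n = n, k = 2L, ms_rows = NA_real_,
                ms_cols = NA_real_, ms_error = NA_real_,
                note = "fewer than 3 complete pairs"))
  }
  if (stats::sd(c(week1, week2)) == 0) {
    return(list(icc = NA_real_, n = n, k = 2L, ms_rows = NA_real_,
                ms_cols = NA_real_, ms_error = NA_real_,
                note = "zero variance"))
  }
  df <- data.frame(value = c(week1, week2),
                   subject = factor(rep(seq_len(n), 2L)),
                   occasion = factor(rep(1:2, each = n)))
  fit <- stats::aov(value ~ subject + occasion, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  k <- 2
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, n = n, k = 2L, ms_rows = msr, ms_cols = msc,
       ms_error = mse, note = NA_character_)
}
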