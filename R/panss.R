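# PANSS item records, subscale totals, the Marder negative symptom factor,
# and the two-visit clinical average.

PANSS_ITEMS <- c(paste0("P", 1:7), paste0("N", 1:7), paste0("G", 1:16))

#' Standard Marder negative-factor item set
#'
#' Five negative-subscale items plus motor retardation (G7) and active
#' social avoidance (G16) per the Marder five-factor solution.
#' @export
MARDER_NEGATIVE_ITEMS <- c("N1", "N2", "N3", "N4", "N6", "G7", "G16")

#' Construct a PANSS record
#'
#' One participant-visit's 30 clinician-rated item scores (P1-P7, N1-N7,
#' G1-G16), each an integer in 1..7.
#'
#' @param participant_id Participant identifier.
#' @param visit_day Integer study day of the visit.
#' @param items Named numeric vector of the 30 item scores.
#' @return An object of class `panss_record`.
#' @export
panss_record <- function(participant_id, visit_day, items) {
  items <- unlist(items)
  miss <- setdiff(PANSS_ITEMS, names(items))
  if (length(miss)) {
    stop("missing PANSS item(s): ", paste(miss, collapse = ", "))
  }
  items <- items[PANSS_ITEMS]
  bad <- PANSS_ITEMS[is.na(items) | items < 1 | items > 7 |
                       items != round(items)]
  if (length(bad)) {
    stop("PANSS item out of range [1, 7]: ", paste(bad, collapse = ", "))
  }
  structure(list(participant_id = as.character(participant_id),
                 visit_day = as.integer(visit_day),
                 items = stats::setNames(as.integer(items), PANSS_ITEMS)),
            class = "panss_record")
}

#' PANSS subscale totals and total score
#'
#' P total is the sum of P1-P7 (range 7-49), N total of N1-N7 (7-49),
#' G total of G1-G16 (16-112); the PANSS total is their sum (30-210). The
#' Marder negative factor is included alongside.
#'
#' @param record A [panss_record()].
#' @param marder_items Item set for the negative factor
#'   (default [MARDER_NEGATIVE_ITEMS]).
#' @return A list of class `clinical_scores`: `p_total`, `n_total`,
#'   `g_total`, `panss_total`, `marder_negative`.
#' @export
panss_totals <- function(record, marder_items = MARDER_NEGATIVE_ITEMS) {
  stopifnot(inherits(record, "panss_record"))
  it <- record$items
  structure(list(
    p_total = sum(it[paste0("P", 1:7)]),
    n_total = sum(it[paste0("N", 1:7)]),
    g_total = sum(it[paste0("G", 1:16)]),
    panss_total = sum(it),
    marder_negative = marder_negative_factor(record, items = marder_items)),
    class = "clinical_scores")
}

#' Marder negative symptom factor
#'
#' Sum of the standard Marder negative-factor items: N1, N2, N3, N4, N6,
#' plus motor retardation (G7) and active social avoidance (G16). The item
#' set is configurable to support alternative factor solutions.
#'
#' @param record A [panss_record()].
#' @param items Item names to sum (default [MARDER_NEGATIVE_ITEMS]).
#' @return Integer factor score.
#' @export
marder_negative_factor <- function(record, items = MARDER_NEGATIVE_ITEMS) {
  stopifnot(inherits(record, "panss_record"))
  miss <- setdiff(items, names(record$items))
  if (length(miss)) {
    stop("unknown PANSS item(s): ", paste(miss, collapse = ", "))
  }
  sum(record$items[items])
}

#' Average derived scores over a participant's visits
#'
#' Derived scores are computed per visit and averaged arithmetically (the
#' two-visit clinical reference; results may be non-integer). A single
#' visit passes through with a warning.
#'
#' @param records List of [panss_record()]s for one participant.
#' @param marder_items Item set for the negative factor.
#' @return A `clinical_scores` list (see [panss_totals()]).
#' @export
average_visits <- function(records, marder_items = MARDER_NEGATIVE_ITEMS) {
  if (inherits(records, "panss_record")) records <- list(records)
  if (!length(records)) stop("no PANSS records to average")
  ids <- unique(vapply(records, function(r) r$participant_id, ""))
  if (length(ids) != 1L) {
    stop("records belong to more than one participant: ",
         paste(ids, collapse = ", "))
  }
  if (length(records) == 1L) {
    warning("single PANSS visit for participant ", ids,
            "; scores passed through unaveraged")
  }
  per_visit <- lapply(records, panss_totals, marder_items = marder_items)
  fields <- c("p_total", "n_total", "g_total", "panss_total",
              "marder_negative")
  out <- lapply(fields, function(f) {
    mean(vapply(per_visit, function(s) as.numeric(s[[f]]), 0))
  })
  structure(stats::setNames(out, fields), class = "clinical_scores")
}

#' Read PANSS item scores from CSV
#'
#' Expects one row per participant-visit with columns `participant_id`,
#' `visit_day`, and the 30 items `P1..P7`, `N1..N7`, `G1..G16`.
#'
#' @param path CSV file path.
#' @return A list of [panss_record()]s.
#' @export
read_panss_csv <- function(path) {
  if (!file.exists(path)) stop("PANSS file not found: ", path)
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("participant_id", "visit_day", PANSS_ITEMS)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing PANSS column(s): ", paste(miss, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    panss_record(df$participant_id[i], df$visit_day[i],
                 stats::setNames(as.numeric(df[i, PANSS_ITEMS]), PANSS_ITEMS))
  })
}

#' Averaged clinical scores per participant
#'
#' @param records List of [panss_record()]s (possibly many participants).
#' @param marder_items Item set for the negative factor.
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_visits`, `p_total`, `n_total`, `g_total`, `panss_total`,
#'   `marder_negative`.
#' @export
clinical_scores_table <- function(records,
                                  marder_items = MARDER_NEGATIVE_ITEMS) {
  ids <- vapply(records, function(r) r$participant_id, "")
  rows <- lapply(split(records, ids), function(rs) {
    s <- suppressWarnings(average_visits(rs, marder_items = marder_items))
    tibble::tibble(participant_id = rs[[1]]$participant_id,
                   n_visits = length(rs),
                   p_total = s$p_total, n_total = s$n_total,
                   g_total = s$g_total, panss_total = s$panss_total,
                   marder_negative = s$marder_negative)
  })
  dplyr::bind_rows(rows)
}
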