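# Internal utilities: missing-marker semantics and scoped RNG.

#' Marker value with missing-reason semantics
#'
#' Degenerate inputs (no voiced frames, silent audio, empty tables) yield a
#' marker that is explicitly "missing with a reason" rather than a bare `NaN`,
#' so downstream aggregation can exclude and audit them.
#'
#' @param value Numeric scalar, or `NA` when missing.
#' @param missing_reason Character reason code when `value` is `NA`, else `NA`.
#' @return A list with elements `value` and `missing_reason`, of class
#'   `marker_value`.
#' @export
marker_value <- function(value = NA_real_, missing_reason = NA_character_) {
  value <- as.numeric(value)
  if (length(value) != 1L) stop("`value` must be a scalar")
  if (is.na(value) && is.na(missing_reason)) {
    stop("a missing marker must carry a reason")
  }
  if (!is.na(value)) missing_reason <- NA_character_
  structure(list(value = value, missing_reason = missing_reason),
            class = "marker_value")
}

#' Is a marker value missing?
#' @param x A [marker_value()].
#' @return Logical scalar.
#' @export
is_missing_marker <- function(x) is.na(x$value)

#' @export
print.marker_value <- function(x, ...) {
  if (is_missing_marker(x)) {
    cat("<missing:", x$missing_reason, ">\n")
  } else {
    cat(format(x$value), "\n")
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
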