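#' Tidy a correlation table
#'
#' @param x A `correlation_table`.
#' @param ... Unused.
#' @return A plain tibble of per-feature results with the table's provenance
#'   (`outcome`, `cohort_tag`, `delineation_kind`) added as columns.
#' @export
tidy.correlation_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$outcome <- attr(x, "outcome_name", exact = TRUE) %||% NA_character_
  out$cohort_tag <- attr(x, "cohort_tag", exact = TRUE) %||% NA_character_
  out$delineation_kind <- attr(x, "delineation_kind", exact = TRUE) %||%
    NA_character_
  out
}

#' Summarize a correlation table in one row
#'
#' @param x A `correlation_table`.
#' @param ... Unused.
#' @return One-row tibble: feature counts, how many correlations were
#'   estimable and significant, and the strongest correlate.
#' @export
glance.correlation_table <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  best <- if (any(!is.na(tbl$r))) which.max(tbl$r) else NA_integer_
  tibble::tibble(
    outcome = attr(x, "outcome_name", exact = TRUE) %||% NA_character_,
    cohort_tag = attr(x, "cohort_tag", exact = TRUE) %||% NA_character_,
    delineation_kind = attr(x, "delineation_kind", exact = TRUE) %||%
      NA_character_,
    n_features = nrow(tbl),
    n_estimable = sum(tbl$estimable),
    n_significant = sum(tbl$significant),
    max_r = if (is.na(best)) NA_real_ else tbl$r[best],
    top_feature = if (is.na(best)) NA_character_ else tbl$name[best]
  )
}

#' Tidy a profile comparison
#'
#' @param x A `profile_comparison` from [compare_profiles()].
#' @param ... Unused.
#' @return One-row tibble with the signed-rank statistic and p-value.
#' @export
tidy.profile_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value, n_pairs = x$n_pairs,
    n_zero = x$n_zero, n_undefined = x$n_undefined, method = x$method,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.profile_comparison
#' @export
glance.profile_comparison <- function(x, ...) tidy.profile_comparison(x)
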