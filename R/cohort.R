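TICI_GRADES <- c("0", "1", "2a", "2b", "3")
TICI_SUCCESSFUL <- c("2b", "3")

#' Build and validate a cohort table
#'
#' A cohort table holds one clinical record per patient: the TICI reperfusion
#' grade assigned after endovascular therapy, and the 3-month NIHSS (0-42) and
#' mRS (0-6) outcome scores. `age` (years) and `sex` (`"F"`/`"M"`) are
#' optional.
#'
#' @param x Data frame with columns `patient_id`, `tici`, `nihss_3m`,
#'   `mrs_3m` and optionally `age`, `sex`.
#' @return A validated tibble with `tici` as a factor over the five grades
#'   `0, 1, 2a, 2b, 3`.
#' @export
cohort_table <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("patient_id", "tici", "nihss_3m", "mrs_3m")
  if (!all(req %in% names(x))) {
    stop("cohort table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  x$patient_id <- as.character(x$patient_id)
  tici_chr <- trimws(as.character(x$tici))
  bad <- which(!tici_chr %in% TICI_GRADES)
  if (length(bad)) {
    stop(
      sprintf("row %d: unknown TICI grade '%s' (expected one of %s)",
              bad[1], tici_chr[bad[1]], paste(TICI_GRADES, collapse = ", ")),
      call. = FALSE
    )
  }
  x$tici <- factor(tici_chr, levels = TICI_GRADES)
  for (col in c("nihss_3m", "mrs_3m")) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v))) {
      stop(sprintf("column %s must be integer-valued and complete", col),
           call. = FALSE)
    }
    x[[col]] <- as.integer(v)
  }
  bad <- which(x$nihss_3m < 0L | x$nihss_3m > 42L)
  if (length(bad)) {
    stop(sprintf("row %d: nihss_3m = %d outside [0, 42]", bad[1],
                 x$nihss_3m[bad[1]]), call. = FALSE)
  }
  bad <- which(x$mrs_3m < 0L | x$mrs_3m > 6L)
  if (length(bad)) {
    stop(sprintf("row %d: mrs_3m = %d outside [0, 6]", bad[1],
                 x$mrs_3m[bad[1]]), call. = FALSE)
  }
  dup <- which(duplicated(x$patient_id))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate patient_id '%s'", dup[1],
                 x$patient_id[dup[1]]), call. = FALSE)
  }
  if ("sex" %in% names(x)) {
    s <- as.character(x$sex)
    if (!all(is.na(s) | s %in% c("F", "M"))) {
      stop("sex must be 'F' or 'M'", call. = FALSE)
    }
    x$sex <- s
  }
  class(x) <- c("cohort_table", class(x))
  x
}

#' Read a cohort table from TSV
#'
#' Expects a header row `patient_id  tici  nihss_3m  mrs_3m` with optional
#' `age` and `sex` columns. Validation failures report the offending row.
#'
#' @param path TSV file path.
#' @return A validated [cohort_table()] tibble.
#' @export
read_cohort <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         patient_id = readr::col_character(),
                         tici = readr::col_character(),
                         .default = readr::col_guess()
                       ))
  cohort_table(x)
}

#' Write a cohort table to TSV
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- tibble::as_tibble(cohort)
  out$tici <- as.character(out$tici)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Dichotomize a cohort by revascularization success
#'
#' Successful revascularization is TICI 2b-3; unsuccessful is TICI 0-2a. The
#' two halves partition the input exactly.
#'
#' @param cohort A [cohort_table()].
#' @return Named list with elements `successful` and `unsuccessful`, each a
#'   [cohort_table()].
#' @examples
#' co <- cohort_table(data.frame(
#'   patient_id = c("p1", "p2", "p3", "p4"),
#'   tici = c("0", "2a", "2b", "3"),
#'   nihss_3m = c(20, 15, 5, 2),
#'   mrs_3m = c(5, 4, 2, 1)
#' ))
#' split_by_tici(co)
#' @export
split_by_tici <- function(cohort) {
  cohort <- cohort_table(cohort)
  ok <- as.character(cohort$tici) %in% TICI_SUCCESSFUL
  list(
    successful = cohort[ok, , drop = FALSE],
    unsuccessful = cohort[!ok, , drop = FALSE]
  )
}
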