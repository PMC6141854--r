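#' Pearson product-moment correlation with explicit degeneracy handling
#'
#' Thin, strict wrapper around the product-moment correlation: errors on
#' length mismatch or fewer than two pairs, and returns `NA` (rather than a
#' warning-laden value) when either vector has zero variance, flagging the
#' correlation as undefined. Sparse regional lesion loads make zero-variance
#' features common, so the undefined case is first-class here.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Percentile-bootstrap confidence interval for a Pearson correlation
#'
#' Draws `n_boot` resamples of the patient index with replacement (pairs
#' resampled jointly), computes the Pearson correlation of each resample, and
#' forms the percentile interval from the empirical `(1-level)/2` and
#' `1-(1-level)/2` quantiles of the retained correlations (linear
#' interpolation between order statistics).
#'
#' Resamples in which either variable is constant have no defined correlation
#' and are dropped; `n_dropped` counts them. With sparse lesion loads a
#' resample can easily select no lesioned patient, so this is reported rather
#' than hidden. If more than half of the resamples are dropped the interval
#' is declared non-estimable (`estimable = FALSE`, `NA` bounds).
#'
#' @param x,y Paired numeric vectors, length >= 2.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; mandatory, so every interval is reproducible.
#'   The caller's RNG state is left untouched.
#' @return List with `ci_low`, `ci_high`, `n_used`, `n_dropped`, `estimable`.
#' @export
bootstrap_ci <- function(x, y, n_boot = 1000, level = 0.95, seed) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for a reproducible bootstrap", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)

  r <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    boot_pearson(x, y, idx)
  })
  n_dropped <- sum(is.na(r))
  r_ok <- r[!is.na(r)]
  if (n_dropped > n_boot / 2) {
    return(list(ci_low = NA_real_, ci_high = NA_real_,
                n_used = length(r_ok), n_dropped = n_dropped,
                estimable = FALSE))
  }
  alpha <- (1 - level) / 2
  q <- unname(stats::quantile(r_ok, c(alpha, 1 - alpha), type = 7))
  list(ci_low = q[1], ci_high = q[2], n_used = length(r_ok),
       n_dropped = n_dropped, estimable = TRUE)
}

# Column-wise Pearson correlation of resampled pairs. `idx` is an n x B
# matrix of row indices; returns B correlations with NA for zero-variance
# columns (centering makes the constant-column case exact).
boot_pearson <- function(x, y, idx) {
  n <- nrow(idx)
  xs <- matrix(x[idx], nrow = n)
  ys <- matrix(y[idx], nrow = n)
  xc <- xs - rep(colMeans(xs), each = n)
  yc <- ys - rep(colMeans(ys), each = n)
  sxx <- colSums(xc * xc)
  syy <- colSums(yc * yc)
  sxy <- colSums(xc * yc)
  r <- ifelse(sxx == 0 | syy == 0, NA_real_, sxy / sqrt(sxx * syy))
  pmin(1, pmax(-1, r))
}

#' Zero-inclusion significance rule for a bootstrap interval
#'
#' A correlation is significant exactly when its confidence interval excludes
#' zero; the interval is closed, so an endpoint exactly at zero is
#' insignificant. No p-value is involved.
#'
#' @param ci_low,ci_high Interval bounds.
#' @return `TRUE` iff `0 < ci_low` or `0 > ci_high`; `FALSE` for undefined
#'   (`NA`) intervals.
#' @export
significance <- function(ci_low, ci_high) {
  ifelse(is.na(ci_low) | is.na(ci_high), FALSE, ci_low > 0 | ci_high < 0)
}

#' Correlate every lesion-load feature with a clinical outcome
#'
#' For each atlas-region load column and for total lesion volume, computes
#' the Pearson correlation with the chosen 3-month outcome score, a
#' percentile-bootstrap confidence interval, and the zero-inclusion
#' significance flag.
#'
#' Each feature gets its own RNG stream derived from `seed` and a stable hash
#' of the feature id, so results for one feature never depend on which other
#' features are present or on column order.
#'
#' @param loads A `load_matrix` tibble from [compute_load_matrix()].
#' @param cohort A [cohort_table()]; rows are matched to `loads` by
#'   `patient_id` (an incomplete match is an error).
#' @param outcome `"nihss_3m"` or `"mrs_3m"`.
#' @param n_boot,level Bootstrap settings, see [bootstrap_ci()].
#' @param seed Master integer seed.
#' @param regions Optional region table (`region_id`, `name`) used to attach
#'   region names.
#' @param cohort_tag Label describing the cohort subset (`"all"`,
#'   `"successful"`, `"unsuccessful"`).
#' @return A tibble of class `correlation_table` with one row per feature
#'   (regions plus `total_volume`): `feature_id`, `name`, `r`, `ci_low`,
#'   `ci_high`, `significant`, `estimable`, `n_boot_used`, `n_boot_dropped`.
#'   Attributes `outcome_name`, `cohort_tag` and `delineation_kind` describe
#'   its provenance.
#' @export
correlate_features <- function(loads, cohort, outcome = c("nihss_3m", "mrs_3m"),
                               n_boot = 1000, level = 0.95, seed,
                               regions = NULL, cohort_tag = "all") {
  outcome <- match.arg(outcome)
  cohort <- cohort_table(cohort)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for a reproducible bootstrap", call. = FALSE)
  }
  loads_tbl <- tibble::as_tibble(loads)
  if (!"patient_id" %in% names(loads_tbl)) {
    stop("`loads` must carry a patient_id column", call. = FALSE)
  }
  if (!setequal(loads_tbl$patient_id, cohort$patient_id)) {
    stop("`loads` and `cohort` cover different patients", call. = FALSE)
  }
  if (nrow(cohort) < 2L) {
    stop("need at least 2 patients to correlate", call. = FALSE)
  }
  aligned <- loads_tbl[match(cohort$patient_id, loads_tbl$patient_id), ]
  y <- as.numeric(cohort[[outcome]])

  feat_cols <- grep("^load_", names(aligned), value = TRUE)
  feature_ids <- c(sub("^load_", "", feat_cols), "total_volume")
  xs <- c(lapply(feat_cols, function(cl) as.numeric(aligned[[cl]])),
          list(as.numeric(aligned$total_volume_ml)))

  rows <- purrr::map2(feature_ids, xs, function(fid, x) {
    r <- pearson_r(x, y)
    if (is.na(r)) {
      ci <- list(ci_low = NA_real_, ci_high = NA_real_, n_used = 0L,
                 n_dropped = as.integer(n_boot), estimable = FALSE)
    } else {
      ci <- bootstrap_ci(x, y, n_boot = n_boot, level = level,
                         seed = feature_seed(seed, fid))
    }
    tibble::tibble(
      feature_id = fid,
      r = r,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      significant = significance(ci$ci_low, ci$ci_high),
      estimable = ci$estimable,
      n_boot_used = as.integer(ci$n_used),
      n_boot_dropped = as.integer(ci$n_dropped)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$name <- feature_name(out$feature_id, regions)
  out <- dplyr::relocate(out, "name", .after = "feature_id")
  structure(
    out,
    class = c("correlation_table", class(out)),
    outcome_name = outcome,
    cohort_tag = cohort_tag,
    delineation_kind = attr(loads, "delineation_kind", exact = TRUE)
  )
}

feature_name <- function(feature_id, regions) {
  name <- ifelse(feature_id == "total_volume", "total lesion volume",
                 paste0("region ", feature_id))
  if (!is.null(regions)) {
    m <- match(suppressWarnings(as.integer(feature_id)), regions$region_id)
    name[!is.na(m)] <- regions$name[m[!is.na(m)]]
  }
  name
}

#' Top-k correlating features
#'
#' Orders features by decreasing correlation; features with undefined `r` are
#' excluded, ties are broken by ascending region id (total volume sorts after
#' the regions on ties), and `k` larger than the number of defined features
#' returns them all. Total lesion volume competes in the ranking like any
#' region.
#'
#' @param table A `correlation_table` from [correlate_features()].
#' @param k Number of features to keep (default 10).
#' @return The ordered subset with a `rank` column prepended.
#' @export
rank_top <- function(table, k = 10) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  tbl <- tibble::as_tibble(table)
  tbl <- tbl[!is.na(tbl$r), , drop = FALSE]
  id_num <- suppressWarnings(as.integer(tbl$feature_id))
  is_total <- tbl$feature_id == "total_volume"
  ord <- order(-tbl$r, is_total, id_num)
  tbl <- tbl[ord[seq_len(min(k, nrow(tbl)))], , drop = FALSE]
  tbl <- tibble::add_column(tbl, rank = seq_len(nrow(tbl)), .before = 1L)
  structure(
    tbl,
    class = c("correlation_table", class(tbl)),
    outcome_name = attr(table, "outcome_name", exact = TRUE),
    cohort_tag = attr(table, "cohort_tag", exact = TRUE),
    delineation_kind = attr(table, "delineation_kind", exact = TRUE)
  )
}

#' Write a correlation table as TSV
#'
#' @param table A `correlation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

# Stable per-feature seed: polynomial byte hash of the feature id combined
# with the master seed, then passed through two Lehmer multiplication rounds
# so that near-identical ids (e.g. sequential patient labels) and
# consecutive master seeds land on unrelated streams. All arithmetic stays
# below 2^53, so the result is exact and platform independent.
feature_seed <- function(master_seed, feature_id) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(as.character(feature_id))) {
    h <- (h * 131 + b) %% m
  }
  h <- (h * 48271) %% m          # mix the id hash before combining, so a
  h <- (h * 48271 + 1) %% m      # +1 shift in the id cannot cancel a +1
  s <- (as.numeric(master_seed) %% m + h) %% m   # shift in the master seed
  s <- (s * 48271) %% m
  as.integer(s)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}
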