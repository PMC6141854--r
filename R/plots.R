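#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a correlation table
#'
#' Point-range chart of the top correlating features: Pearson r with its
#' bootstrap confidence interval, colored by the zero-exclusion significance
#' flag.
#'
#' @param object A `correlation_table` from [correlate_features()] or
#'   [rank_top()].
#' @param k Number of top features shown (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_table <- function(object, k = 10, ...) {
  top <- if ("rank" %in% names(object)) object else rank_top(object, k)
  top <- tibble::as_tibble(top)
  top$name <- factor(top$name, levels = rev(top$name))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$r, y = .data$name,
                                    color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey40"),
      labels = c(`TRUE` = "CI excludes 0", `FALSE` = "CI includes 0"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "Pearson r (with bootstrap CI)", y = NULL,
      title = sprintf("Top lesion-load correlates, %s (%s)",
                      attr(object, "outcome_name", exact = TRUE) %||% "",
                      attr(object, "cohort_tag", exact = TRUE) %||% "all")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a lesion-frequency (or any scalar) map
#'
#' @param map A [scalar_map()].
#' @param z Axial slice index (defaults to the middle slice).
#' @return A ggplot object.
#' @export
plot_frequency_map <- function(map, z = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  d <- map$grid$shape
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- map$data[, , z]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "frequency") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("axial slice z = %d", z), x = NULL,
                  y = NULL) +
    ggplot2::theme_void()
}

#' Plot a lesion-load matrix as a heatmap
#'
#' @param object A `load_matrix` from [compute_load_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.load_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("load_"),
    names_to = "region", values_to = "load", names_prefix = "load_"
  )
  long$region <- factor(long$region,
                        levels = as.character(sort(as.integer(unique(long$region)))))
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$patient_id,
                                     fill = .data$load)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "load (%)") +
    ggplot2::labs(x = "atlas region", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
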