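#' @export
print.benchmark_report <- function(x, ...) {
  cat("Annotation-transfer benchmark:", x$n_queries, "queries,",
      x$n_families, "families, weighting by", x$weight_side, "side\n")
  print(x$report)
  invisible(x)
}

#' Tidy methods for benchmark objects
#'
#' `tidy()` on a `benchmark_report` returns the per-threshold metrics in
#' long form; `glance()` returns a one-row summary at the best-F threshold.
#' `tidy()` on a `pwm_motif` returns the position/residue probabilities in
#' long form.
#'
#' @param x A `benchmark_report` or `pwm_motif`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.benchmark_report <- function(x, ...) {
  tidyr::pivot_longer(x$report, -"threshold",
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  best <- x$report[which.max(x$report$f_measure), ]
  tibble(best_threshold = best$threshold,
         best_f_measure = best$f_measure,
         precision_at_best = best$precision,
         recall_at_best = best$recall,
         unclassified_at_best = best$unclassified,
         n_queries = x$n_queries,
         n_families = x$n_families)
}

#' Plot methods for benchmark objects
#'
#' `autoplot()` on a `benchmark_report` draws precision, recall, F-measure
#' and the unclassified fraction against the (log-scaled) normalized E-value
#' threshold. On a `substrate_crosstab` it draws the family-by-family match
#' heatmap on the benchmark's logarithmic grayscale (white: no match better
#' than the loosest threshold; black: best match beyond the strictest).
#'
#' @param object A `benchmark_report` or `substrate_crosstab`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_report <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = -log10(.data$threshold),
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "-log10 normalized E-value threshold (loose to strict)",
                  y = "percent", colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.benchmark_report
#' @export
autoplot.substrate_crosstab <- function(object, ...) {
  tab <- object$table
  n_bins <- length(object$grid) - 1
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$target_family,
                                    y = .data$query_family,
                                    fill = .data$bin)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, n_bins), na.value = "white") +
    ggplot2::labs(x = "reference families", y = "query families",
                  fill = "match bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
print.substrate_crosstab <- function(x, ...) {
  cat("substrate_TC cross-tabulation over", length(unique(x$table$query_family)),
      "query and", length(unique(x$table$target_family)), "reference families\n")
  print(x$table)
  invisible(x)
}

#' Write a crosstab table to TSV
#'
#' @param crosstab A `substrate_crosstab`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(crosstab, path) {
  readr::write_tsv(crosstab$table, path)
  invisible(path)
}
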