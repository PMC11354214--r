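#' Variant sequence-map plot
#'
#' Number of variants per residue position, coloured by fold region --
#' the cohort-overview figure for a variant set.
#'
#' @param reports impact-report tibble (needs `position`; `region` used
#'   when present) or any tibble with a `position` column.
#' @param annotation optional `region_annotation` used to colour positions
#'   when `reports` has no `region` column.
#' @return a ggplot object.
#' @export
plot_variant_map <- function(reports, annotation = NULL) {
  df <- tibble::as_tibble(reports)
  if (!"region" %in% names(df)) {
    df$region <- if (!is.null(annotation)) region_of(df$position, annotation)
                 else "unassigned"
  }
  counts <- dplyr::count(df, .data$position, .data$region, name = "n")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$position, y = .data$n,
                                       fill = .data$region)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "residue position (precursor numbering)",
                  y = "missense variants", fill = "region") +
    ggplot2::theme_minimal()
}

#' Cohort impact-summary plot
#'
#' Bar chart of the per-parameter change counts of a cohort summary.
#'
#' @param object a `cohort_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  td <- tidy.cohort_summary(object)
  td <- td[!is.na(td$n) & td$metric != "n_variants", ]
  td$metric <- sub("^n_", "", td$metric)
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$metric, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "variants") +
    ggplot2::theme_minimal()
}
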