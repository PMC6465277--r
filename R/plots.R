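#' Figures for stratified constraint, odds ratios and enrichment
#'
#' Lightweight ggplot2 views of the result tibbles; each takes the tidy
#' output of the corresponding analysis function and returns a ggplot object
#' the caller can theme further.
#'
#' @name plots
NULL

#' Bar chart of constraint proportions by inheritance class
#'
#' @param tbl Output of [constraint_by_inheritance()].
#' @param measure Which proportion to show: `"missense"`, `"lof"` or
#'   `"regional_only"`.
#' @return A ggplot object.
#' @export
plot_constraint_by_inheritance <- function(tbl, measure = c("missense", "lof",
                                                            "regional_only")) {
  measure <- match.arg(measure)
  col <- paste0("pct_", measure)
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = factor(.data$inheritance_class,
               INHERITANCE_CLASSES[INHERITANCE_CLASSES %in%
                                     tbl$inheritance_class]),
    y = .data[[col]])) +
    ggplot2::geom_col(fill = "#d95f02") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data[[paste0("n_", measure)]], .data$n)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Inheritance class",
                  y = sprintf("%% of scored genes (%s constraint)",
                              sub("_", " ", measure))) +
    ggplot2::theme_minimal()
}

#' Forest plot of feature odds ratios
#'
#' @param tbl Output of [association_odds_ratios()] (columns `feature`,
#'   `estimate`, `conf.low`, `conf.high`).
#' @return A ggplot object (log-scaled x axis, reference line at OR = 1).
#' @export
plot_odds_ratios <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$feature,
                                                       .data$estimate))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of enriched GO-slim terms
#'
#' @param tbl Output of [hypergeom_enrichment()].
#' @param max_terms Number of top terms to show per namespace.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(tbl, max_terms = 10L) {
  top <- tbl |>
    group_by(.data$namespace) |>
    dplyr::slice_min(.data$q_bh, n = max_terms, with_ties = FALSE) |>
    ungroup()
  ggplot2::ggplot(top, ggplot2::aes(x = .data$k / .data$n,
                                    y = stats::reorder(.data$go_id,
                                                       -.data$q_bh),
                                    size = .data$k,
                                    colour = -log10(.data$q_bh))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$namespace), scales = "free_y") +
    ggplot2::labs(x = "Study-set annotation fraction", y = NULL,
                  size = "Hits", colour = "-log10 q") +
    ggplot2::theme_minimal()
}
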