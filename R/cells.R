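#' Cell essentialome aggregation
#'
#' Per-cell-line essentiality calls from three genome-wide knockout screens
#' are aggregated into one summary per gene. Distinct cell lines (not
#' study-line pairs) are counted: a line screened by two studies counts once
#' and is essential if any study called it essential.
#'
#' @name cell-essentiality
NULL

#' Aggregate per-line essentiality calls into a per-gene essentialome summary
#'
#' @param calls Call tibble (`symbol`, `cell_line`, `study`, `essential`,
#'   `tested`) with at most one call per (symbol, cell_line, study).
#' @param min_lines Minimum number of distinct essential cell lines for the
#'   aggregated essential flag (default 3).
#' @param n_lines_total Total number of cell lines in the screen set (default:
#'   number of distinct lines observed in `calls`); `essential_all_lines`
#'   requires a tested, essential call in every one.
#' @return A tibble with one row per gene: `n_lines_tested`,
#'   `n_lines_essential`, `essential_agg`, `essential_all_lines`.
#' @export
aggregate_essentialome <- function(calls, min_lines = 3L,
                                   n_lines_total = dplyr::n_distinct(calls$cell_line)) {
  if (!is.numeric(min_lines) || length(min_lines) != 1L || min_lines < 1) {
    abort("min_lines must be a single integer >= 1",
          class = "devlethal_parameter_error")
  }
  dup <- calls |>
    count(.data$symbol, .data$cell_line, .data$study) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate (symbol, cell_line, study) call(s), e.g. %s / %s",
                  dup$symbol[[1L]], dup$cell_line[[1L]]),
          class = "devlethal_validation_error")
  }
  calls |>
    filter(.data$tested) |>
    group_by(.data$symbol, .data$cell_line) |>
    summarise(essential = any(.data$essential), .groups = "drop") |>
    group_by(.data$symbol) |>
    summarise(
      n_lines_tested = dplyr::n(),
      n_lines_essential = sum(.data$essential),
      .groups = "drop"
    ) |>
    mutate(
      essential_agg = .data$n_lines_essential >= min_lines,
      essential_all_lines = .data$n_lines_tested == n_lines_total &
        .data$n_lines_essential == n_lines_total
    )
}

#' Genes tested in all three studies
#'
#' The essentialome analyses are restricted to genes assayed by every study;
#' this returns that restriction of the universe.
#'
#' @param universe Universe tibble (or character vector of symbols).
#' @param calls Call tibble with `tested` flags.
#' @return Character vector of symbols tested (in at least one line) in each
#'   distinct study present in `calls`.
#' @export
restrict_to_tested <- function(universe, calls) {
  symbols <- if (is.data.frame(universe)) universe$symbol else universe
  if (nrow(calls) == 0L) return(character(0))
  n_studies <- dplyr::n_distinct(calls$study)
  tested <- calls |>
    filter(.data$tested, .data$symbol %in% symbols) |>
    distinct(.data$symbol, .data$study) |>
    count(.data$symbol) |>
    filter(.data$n == n_studies)
  tested$symbol
}
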