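#' Genetic-constraint categorisation
#'
#' Whole-gene constraint uses the recommended gnomAD cutoffs: missense
#' z-score of at least 3.09 or pLI of at least 0.9 (both thresholds
#' inclusive). Regional constraint is
#' membership in the union of three published gene lists (gamma <= 0.6
#' regional missense constraint, coding-constrained-region 99th percentile,
#' NMD-escape truncation depletion); the lists are consumed, not recomputed.
#' Scored genes fall in exactly one of `whole_gene`, `regional_only`, `none`;
#' genes with no scores are `no_data` and drop out of constraint denominators.
#'
#' @name constraint
NULL

#' Classify whole-gene constraint from gnomAD-style scores
#'
#' @param scores Tibble with `symbol`, `mis_z`, `pLI` (one row per gene).
#' @param mis_threshold Missense z cutoff (inclusive; default 3.09).
#' @param pli_threshold pLI cutoff (inclusive; default 0.9).
#' @return `scores` with logical `missense_constrained`, `lof_constrained`
#'   and `has_scores` columns bound on (both flags NA when scores absent).
#' @export
classify_whole_gene <- function(scores, mis_threshold = 3.09,
                                pli_threshold = 0.9) {
  assert_cols(scores, c("symbol", "mis_z", "pLI"), "constraint score table")
  mutate(
    scores,
    has_scores = !is.na(.data$mis_z) | !is.na(.data$pLI),
    missense_constrained = if_else(.data$has_scores,
                                   dplyr::coalesce(.data$mis_z >= mis_threshold,
                                                   FALSE), NA),
    lof_constrained = if_else(.data$has_scores,
                              dplyr::coalesce(.data$pLI >= pli_threshold,
                                              FALSE), NA)
  )
}

#' Aggregate regional-constraint membership across the three metrics
#'
#' @param gamma_set,ccr_set,nmd_set Character vectors of gene symbols flagged
#'   by each regional-constraint metric.
#' @return A tibble (`symbol`, `regional_constrained`) over the union, with
#'   `regional_constrained = TRUE` for membership in at least one metric.
#' @export
aggregate_regional <- function(gamma_set, ccr_set, nmd_set) {
  tibble(symbol = union(union(gamma_set, ccr_set), nmd_set),
         regional_constrained = TRUE)
}

#' Combine whole-gene and regional constraint into categories
#'
#' @param scores Constraint score tibble (genes absent from it are `no_data`).
#' @param regional Tibble from [aggregate_regional()] (or a character vector
#'   of regionally constrained symbols).
#' @param universe Optional universe (tibble or character) to report genes
#'   with no score row as `no_data`.
#' @inheritParams classify_whole_gene
#' @return A tibble keyed by symbol with `missense_constrained`,
#'   `lof_constrained`, `regional_constrained`, `has_scores` and
#'   `constraint_category` in `r paste(CONSTRAINT_CATEGORIES, collapse = "/")`.
#' @export
constraint_categories <- function(scores, regional = character(0),
                                  universe = NULL, mis_threshold = 3.09,
                                  pli_threshold = 0.9) {
  if (is.character(regional)) {
    regional <- tibble(symbol = unique(regional), regional_constrained = TRUE)
  }
  scored <- classify_whole_gene(scores, mis_threshold, pli_threshold)
  if (!is.null(universe)) {
    symbols <- if (is.data.frame(universe)) universe$symbol else universe
    scored <- left_join(tibble(symbol = symbols), scored, by = "symbol") |>
      mutate(has_scores = dplyr::coalesce(.data$has_scores, FALSE))
  }
  scored |>
    left_join(regional, by = "symbol") |>
    mutate(
      regional_constrained = dplyr::coalesce(.data$regional_constrained, FALSE),
      constraint_category = case_when(
        !.data$has_scores ~ "no_data",
        .data$missense_constrained | .data$lof_constrained ~ "whole_gene",
        .data$regional_constrained ~ "regional_only",
        .default = "none"
      )
    ) |>
    select("symbol", "mis_z", "pLI", "has_scores", "missense_constrained",
           "lof_constrained", "regional_constrained", "constraint_category")
}
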