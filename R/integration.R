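#' Master-table assembly and candidate derivation
#'
#' All evidence streams are joined onto the protein-coding universe, one row
#' per gene, with absent evidence encoded as `NA` (no data), never as `FALSE`.
#' The candidate developmental-lethal set is the genes essential for murine
#' development (recessive-knockout lethal) or cellular viability (aggregated
#' essentialome) that are not in the clinically relevant disease-gene set.
#'
#' @name integration
NULL

#' Build the integrated per-gene master table
#'
#' @param universe Universe tibble from [read_gene_universe()].
#' @param curated Curated disease genes from [filter_clinically_relevant()].
#' @param mouse_calls Per-gene calls from [classify_mouse_lethal()].
#' @param cell_summaries Per-gene summaries from [aggregate_essentialome()].
#' @param cell_tested Optional character vector of genes tested in all three
#'   studies (from [restrict_to_tested()]); defaults to the genes present in
#'   `cell_summaries`.
#' @param constraint_cats Per-gene categories from [constraint_categories()].
#' @return A tibble with exactly one row per universe gene. Logical evidence
#'   columns are `NA` where the source had no data for the gene;
#'   `candidate_dev_lethal` is `TRUE` iff (`mouse_lethal` or `essential_agg`)
#'   and the gene is not OMIM-clinical.
#' @export
build_master <- function(universe, curated, mouse_calls, cell_summaries,
                         constraint_cats, cell_tested = cell_summaries$symbol) {
  dup <- universe$symbol[duplicated(universe$symbol)]
  if (length(dup) > 0L) {
    abort(sprintf("universe symbol collision(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "devlethal_validation_error")
  }
  for (nm in c("curated", "mouse_calls", "cell_summaries", "constraint_cats")) {
    tbl <- get(nm)
    if (anyDuplicated(tbl$symbol) > 0L) {
      abort(sprintf("%s has more than one row per symbol", nm),
            class = "devlethal_validation_error")
    }
  }

  master <- tibble(symbol = universe$symbol) |>
    left_join(curated |>
                mutate(is_omim_clinical = TRUE) |>
                select("symbol", "is_omim_clinical", "inheritance_class",
                       "lethal_class"),
              by = "symbol") |>
    left_join(mouse_calls |>
                select("symbol", mouse_lethal = "lethal_recessive",
                       mouse_stage = "stage", "outside_recessive_filter",
                       "premature_death"),
              by = "symbol") |>
    left_join(cell_summaries |>
                select("symbol", "n_lines_tested", "n_lines_essential",
                       "essential_agg", "essential_all_lines"),
              by = "symbol") |>
    left_join(constraint_cats |>
                select("symbol", "has_scores", "missense_constrained",
                       "lof_constrained", "regional_constrained",
                       constraint_category = "constraint_category"),
              by = "symbol") |>
    mutate(
      is_omim_clinical = dplyr::coalesce(.data$is_omim_clinical, FALSE),
      lethal_class = if_else(.data$is_omim_clinical,
                             dplyr::coalesce(.data$lethal_class, "none"),
                             NA_character_),
      mouse_data = !is.na(.data$mouse_lethal),
      cell_data = .data$symbol %in% cell_tested,
      # the essentialome is defined on the universe tested by every study;
      # calls on partially screened genes are treated as no data
      dplyr::across(c("n_lines_tested", "n_lines_essential", "essential_agg",
                      "essential_all_lines"),
                    ~ if_else(.data$cell_data, .x, NA)),
      has_scores = dplyr::coalesce(.data$has_scores, FALSE),
      constraint_category = dplyr::coalesce(.data$constraint_category,
                                            "no_data"),
      candidate_dev_lethal =
        (dplyr::coalesce(.data$mouse_lethal, FALSE) |
           dplyr::coalesce(.data$essential_agg, FALSE)) &
        !.data$is_omim_clinical
    ) |>
    relocate("symbol", "is_omim_clinical", "inheritance_class", "lethal_class",
             "mouse_data", "mouse_lethal", "mouse_stage",
             "outside_recessive_filter", "premature_death",
             "cell_data", "n_lines_tested", "n_lines_essential",
             "essential_agg", "essential_all_lines",
             "has_scores", "missense_constrained", "lof_constrained",
             "regional_constrained", "constraint_category",
             "candidate_dev_lethal")
  master
}

#' Derive the candidate developmental-lethal gene set
#'
#' @param master Master table from [build_master()].
#' @return Character vector of candidate gene symbols: essential for murine
#'   development or cellular viability and not OMIM-clinical. Genes with
#'   neither mouse nor cell data can never be candidates (no evidence is not
#'   negative evidence).
#' @export
derive_candidates <- function(master) {
  master$symbol[(master$mouse_lethal %in% TRUE |
                   master$essential_agg %in% TRUE) &
                  !master$is_omim_clinical]
}

#' Venn-region counts for the mouse/cell essentialome overlap
#'
#' Counts the mouse-lethal-only, cell-essential-only, both and neither
#' regions, split by OMIM-clinical status. With
#' `restrict_to_both_data = FALSE` the denominator is every gene carrying
#' mouse or cell data; with `TRUE` every count is recomputed on the subset
#' with both kinds of data.
#'
#' @param master Master table.
#' @param restrict_to_both_data Restrict to genes with both mouse and cell
#'   data?
#' @return A tibble (`region`, `omim`, `non_omim`, `total`) whose regions
#'   partition the denominator; the denominator size is attached as attribute
#'   `"n_universe"`.
#' @export
overlap_summary <- function(master, restrict_to_both_data = FALSE) {
  base <- if (restrict_to_both_data) {
    filter(master, .data$mouse_data & .data$cell_data)
  } else {
    filter(master, .data$mouse_data | .data$cell_data)
  }
  base <- mutate(
    base,
    m = .data$mouse_lethal %in% TRUE,
    c = .data$essential_agg %in% TRUE,
    region = case_when(
      .data$m & .data$c ~ "mouse_and_cell",
      .data$m ~ "mouse_only",
      .data$c ~ "cell_only",
      .default = "neither"
    )
  )
  out <- base |>
    group_by(region = factor(.data$region,
                             c("mouse_and_cell", "mouse_only", "cell_only",
                               "neither"))) |>
    summarise(omim = sum(.data$is_omim_clinical),
              non_omim = sum(!.data$is_omim_clinical),
              .groups = "drop") |>
    tidyr::complete(.data$region, fill = list(omim = 0L, non_omim = 0L)) |>
    mutate(region = as.character(.data$region),
           total = .data$omim + .data$non_omim)
  attr(out, "n_universe") <- nrow(base)
  out
}
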