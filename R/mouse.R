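#' Mouse knockout lethality classification
#'
#' Genes are called mouse-lethal when a recessive (homozygous) null/knockout
#' or hypomorph allele affecting a single gene carries at least one lethal
#' Mammalian Phenotype (MP) term; lethality seen only through heterozygous
#' knockouts or non-null alleles is reported separately as falling outside the
#' recessive-null filter. Each lethal gene is staged by the earliest
#' developmental stage among its matched terms; premature-death terms are
#' tracked but never set the lethal flag.
#'
#' @name mouse-lethality
NULL

#' Default lethal MP term set, partitioned by stage
#'
#' The curated term list the classifier queries is data: this default covers
#' the core lethality families of the Mammalian Phenotype Ontology, grouped by
#' the stage of death, plus the premature-death term. It can be replaced or
#' extended via [read_lethal_terms()]; matching is by explicit ID membership
#' (no ontology-descendant closure).
#'
#' @return A list with `lethal_terms` (named list stage -> MP IDs, stages
#'   ordered from earliest) and `premature_death_terms`.
#' @export
default_lethal_terms <- function() {
  list(
    lethal_terms = list(
      embryonic = c("MP:0008762",  # embryonic lethality
                    "MP:0011092",  # complete embryonic lethality
                    "MP:0011098",  # complete embryonic lethality before implantation
                    "MP:0011096",  # complete embryonic lethality before organogenesis
                    "MP:0011094"), # complete embryonic lethality before somite formation
      prenatal = c("MP:0002080",   # prenatal lethality
                   "MP:0011088",   # complete prenatal lethality
                   "MP:0006207"),  # embryonic lethality during organogenesis
      perinatal = c("MP:0002081",  # perinatal lethality
                    "MP:0011090",  # complete perinatal lethality
                    "MP:0002082"), # neonatal lethality
      preweaning_postnatal = c("MP:0011100",  # preweaning lethality, complete penetrance
                               "MP:0011110",  # preweaning lethality, incomplete penetrance
                               "MP:0010770")  # preweaning lethality
    ),
    premature_death_terms = "MP:0002083"  # premature death
  )
}

validate_lethal_terms <- function(terms) {
  stopifnot(is.list(terms), "lethal_terms" %in% names(terms))
  stages <- names(terms$lethal_terms)
  bad <- stages[stages %notin% setdiff(STAGE_LEVELS, c("premature_death", "none"))]
  if (length(bad) > 0L) {
    abort(sprintf("unknown lethality stage(s): %s", paste(bad, collapse = ", ")),
          class = "devlethal_validation_error")
  }
  all_ids <- c(unlist(terms$lethal_terms), terms$premature_death_terms)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup) > 0L) {
    abort(sprintf("MP term(s) assigned to more than one stage: %s",
                  paste(dup, collapse = ", ")),
          class = "devlethal_validation_error")
  }
  terms$premature_death_terms <- terms$premature_death_terms %||% character(0)
  terms
}

#' Load a lethal term set from YAML
#'
#' @param path YAML file with a `lethal_terms` mapping (stage -> list of MP
#'   IDs) and optional `premature_death_terms`.
#' @return A validated term-set list.
#' @export
read_lethal_terms <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$lethal_terms <- purrr::map(raw$lethal_terms, unlist)
  raw$premature_death_terms <- unlist(raw$premature_death_terms)
  validate_lethal_terms(raw)
}

#' Restrict knockout records to the recessive-null-eligible subset
#'
#' Keeps alleles that affect exactly one gene and are annotated null/knockout
#' or hypomorph. With `homozygous_only = TRUE` the records are additionally
#' restricted to homozygous genotypes (the recessive analysis path).
#'
#' @param records Parsed records from [read_mouse_phenotypes()].
#' @param homozygous_only Restrict to `zygosity == "hom"`?
#' @return The eligible subset of `records`.
#' @export
filter_eligible <- function(records, homozygous_only = FALSE) {
  out <- filter(records,
                .data$n_genes_affected == 1L,
                .data$allele_attribute %in% c("null_knockout", "hypomorph"))
  if (homozygous_only) out <- filter(out, .data$zygosity == "hom")
  out
}

match_stage <- function(mp_terms, stage_of) {
  # earliest (most severe) stage among matched lethal terms, or "none"
  hits <- stage_of[unlist(mp_terms)]
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0L) return("none")
  STAGE_LEVELS[min(match(hits, STAGE_LEVELS))]
}

#' Classify per-gene mouse lethality
#'
#' @param records Parsed knockout records (all zygosities; eligibility is
#'   applied internally via [filter_eligible()]).
#' @param terms A lethal term set (default [default_lethal_terms()]).
#' @return A tibble with one row per gene: `lethal_recessive` (lethal term on
#'   an eligible homozygous record), `lethal_any_zygosity` (lethal term on any
#'   single-gene record; multi-gene alleles are ignored on every route),
#'   `outside_recessive_filter` (lethal only via heterozygous or
#'   non-eligible routes), `stage`, `premature_death`, `hom_data` (has an
#'   eligible homozygous record), `sources_with_data` (list-column). Unknown
#'   MP terms are ignored for classification and tallied in the
#'   `"term_report"` attribute.
#' @export
classify_mouse_lethal <- function(records, terms = default_lethal_terms()) {
  terms <- validate_lethal_terms(terms)
  lethal_ids <- unlist(terms$lethal_terms, use.names = FALSE)
  stage_of <- setNames(
    rep(names(terms$lethal_terms), lengths(terms$lethal_terms)),
    lethal_ids)

  eligible_hom <- filter_eligible(records, homozygous_only = TRUE)

  flat <- records |>
    mutate(.row = dplyr::row_number()) |>
    tidyr::unnest_longer("mp_terms", values_to = "mp_term", keep_empty = TRUE)

  flat <- mutate(
    flat,
    is_lethal_term = .data$mp_term %in% lethal_ids,
    is_premature = .data$mp_term %in% terms$premature_death_terms,
    # multi-gene alleles cannot attribute the phenotype to one gene and are
    # excluded from every classification route
    single_gene = .data$n_genes_affected == 1L,
    eligible = .data$single_gene &
      .data$allele_attribute %in% c("null_knockout", "hypomorph"),
    recessive_path = .data$eligible & .data$zygosity == "hom"
  )

  per_gene <- flat |>
    group_by(.data$symbol) |>
    summarise(
      lethal_recessive = any(.data$recessive_path & .data$is_lethal_term,
                             na.rm = TRUE),
      lethal_any_zygosity = any(.data$single_gene & .data$is_lethal_term,
                                na.rm = TRUE),
      premature_death = any(.data$recessive_path & .data$is_premature,
                            na.rm = TRUE),
      stage_recessive = match_stage(
        list(.data$mp_term[.data$recessive_path & .data$is_lethal_term]),
        stage_of),
      stage_any = match_stage(
        list(.data$mp_term[.data$single_gene & .data$is_lethal_term]),
        stage_of),
      sources_with_data = list(sort(unique(.data$source))),
      .groups = "drop"
    ) |>
    mutate(
      outside_recessive_filter = .data$lethal_any_zygosity &
        !.data$lethal_recessive,
      stage = if_else(.data$lethal_recessive, .data$stage_recessive,
                      if_else(.data$lethal_any_zygosity, .data$stage_any,
                              "none")),
      hom_data = .data$symbol %in% eligible_hom$symbol
    ) |>
    select("symbol", "lethal_recessive", "lethal_any_zygosity",
           "outside_recessive_filter", "stage", "premature_death",
           "hom_data", "sources_with_data")

  known <- c(lethal_ids, terms$premature_death_terms)
  unknown <- setdiff(unique(flat$mp_term[!is.na(flat$mp_term)]), known)
  attr(per_gene, "term_report") <- list(
    n_unknown_terms = length(unknown),
    unknown_terms = unknown
  )
  per_gene
}

#' Cross-source concordance of recessive lethality calls
#'
#' Over the genes carrying an eligible homozygous-knockout call in both
#' sources, the fraction whose `lethal_recessive` flags agree.
#'
#' @param calls_mgi,calls_impc Per-source call tibbles from
#'   [classify_mouse_lethal()].
#' @return A list with `concordance` (fraction in \[0, 1\]) and `n_shared`.
#' @export
cross_source_concordance <- function(calls_mgi, calls_impc) {
  shared <- inner_join(
    filter(calls_mgi, .data$hom_data) |>
      select("symbol", mgi = "lethal_recessive"),
    filter(calls_impc, .data$hom_data) |>
      select("symbol", impc = "lethal_recessive"),
    by = "symbol")
  if (nrow(shared) == 0L) {
    abort("no genes with homozygous-knockout data in both sources",
          class = "devlethal_validation_error")
  }
  list(concordance = mean(shared$mgi == shared$impc),
       n_shared = nrow(shared))
}
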