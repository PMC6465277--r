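#' Run the full gene-discovery pipeline on a source bundle
#'
#' Convenience driver chaining every stage: genemap parsing and disease-gene
#' curation, mouse lethality classification, essentialome aggregation,
#' constraint categorisation, master-table assembly and candidate derivation.
#'
#' @param bundle A source bundle as returned by [read_source_bundle()] or in
#'   the `bundle` element of [generate_sources()] (with `mgi`/`impc` either
#'   separate or pre-bound as `mouse`).
#' @param lexicon Lethality lexicon for the clinical-text tier flags.
#' @param terms Lethal MP term set for the mouse classifier.
#' @param min_lines Essentialome cell-line threshold (default 3).
#' @param overrides Optional manual-review override table passed to
#'   [filter_clinically_relevant()].
#' @return A list: `master` (the integrated table), `curated`, `mouse_calls`,
#'   `cell_summaries`, `constraint`, `candidates` (character vector).
#' @export
run_pipeline <- function(bundle, lexicon = default_lethality_lexicon(),
                         terms = default_lethal_terms(), min_lines = 3L,
                         overrides = NULL) {
  mouse_records <- bundle$mouse %||% bind_rows(bundle$mgi, bundle$impc)

  universe <- bundle$universe
  if (is.data.frame(universe) && "locus_type" %in% names(universe)) {
    universe <- filter(universe, .data$locus_type == "protein-coding")
  }

  curated <- filter_clinically_relevant(parse_genemap(bundle$genemap),
                                        universe, lexicon = lexicon,
                                        overrides = overrides)
  mouse_calls <- classify_mouse_lethal(mouse_records, terms = terms)
  cell_summaries <- aggregate_essentialome(bundle$essentiality,
                                           min_lines = min_lines)
  cell_tested <- restrict_to_tested(universe, bundle$essentiality)
  regional <- aggregate_regional(bundle$regional$gamma, bundle$regional$ccr,
                                 bundle$regional$nmd)
  constraint <- constraint_categories(bundle$constraint, regional,
                                      universe = universe)
  master <- build_master(universe, curated, mouse_calls,
                         cell_summaries, constraint,
                         cell_tested = cell_tested)
  list(master = master, curated = curated, mouse_calls = mouse_calls,
       cell_summaries = cell_summaries, constraint = constraint,
       candidates = derive_candidates(master))
}
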