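#' Read and validate the tabular source dumps
#'
#' All sources are tab-separated files with a single header row; lines
#' beginning with `#` are comments. Gene symbols are matched case-sensitively
#' after whitespace trimming; no alias resolution is attempted, and symbols in
#' evidence tables that do not match the protein-coding universe are reported
#' by the downstream joins rather than treated as fatal.
#'
#' @name source-io
NULL

read_source_tsv <- function(path, col_types = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("source file does not exist: %s", path),
          class = "devlethal_io_error")
  }
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

#' Read the protein-coding gene universe
#'
#' Reads an HGNC-style gene table and retains only protein-coding loci, which
#' define the universe every downstream stage is restricted to. Input order is
#' preserved; duplicated symbols are a validation error because the symbol is
#' the key of every other table.
#'
#' @param path Path to a TSV with columns `symbol`, `gene_id`, `locus_type`,
#'   `chromosome`.
#' @return A tibble with one row per protein-coding gene.
#' @export
read_gene_universe <- function(path) {
  raw <- read_source_tsv(path, readr::cols(.default = readr::col_character()))
  assert_cols(raw, c("symbol", "locus_type"), "gene universe table")
  raw <- mutate(raw, symbol = stringr::str_trim(.data$symbol))
  universe <- filter(raw, .data$locus_type == "protein-coding")
  dup <- universe$symbol[duplicated(universe$symbol)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicated gene symbol(s) in universe: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "devlethal_validation_error")
  }
  if (!"gene_id" %in% names(universe)) universe$gene_id <- universe$symbol
  if (!"chromosome" %in% names(universe)) universe$chromosome <- NA_character_
  select(universe, "symbol", "gene_id", "locus_type", "chromosome")
}

#' Read a genemap-style disease-phenotype table
#'
#' One row per (gene, phenotype assertion). The phenotype string carries the
#' mapping key and modifier syntax parsed by [parse_phenotype_string()]; the
#' optional `clinical_synopsis` column carries the free text mined for
#' lethality wording.
#'
#' @param path Path to a TSV with columns `symbol`, `phenotype` and optionally
#'   `clinical_synopsis`.
#' @return A tibble of raw phenotype rows.
#' @export
read_genemap <- function(path) {
  raw <- read_source_tsv(path, readr::cols(.default = readr::col_character()))
  assert_cols(raw, c("symbol", "phenotype"), "genemap table")
  if (!"clinical_synopsis" %in% names(raw)) raw$clinical_synopsis <- NA_character_
  mutate(raw, symbol = stringr::str_trim(.data$symbol))
}

MP_TERM_RE <- "^MP:[0-9]{7}$"

#' Read mouse knockout phenotype records
#'
#' Parses an MGI- or IMPC-style report into one record per genotype row. MP
#' term identifiers are semicolon-separated; terms that do not match the
#' `MP:` + 7-digit pattern are dropped with a warning and tallied in the parse
#' report attached as attribute `"parse_report"`.
#'
#' @param path Path to a TSV with columns `symbol`, `allele_attribute`,
#'   `n_genes_affected`, `zygosity`, `mp_terms`.
#' @param source Which resource the report came from: `"MGI"` or `"IMPC"`.
#' @return A tibble with `mp_terms` as a list-column of character vectors and
#'   a stamped `source` column.
#' @export
read_mouse_phenotypes <- function(path, source = c("MGI", "IMPC")) {
  source <- match.arg(source)
  raw <- read_source_tsv(path, readr::cols(
    symbol = readr::col_character(),
    allele_attribute = readr::col_character(),
    n_genes_affected = readr::col_integer(),
    zygosity = readr::col_character(),
    mp_terms = readr::col_character()
  ))
  assert_cols(raw, c("symbol", "allele_attribute", "n_genes_affected",
                     "zygosity", "mp_terms"), "mouse phenotype table")
  terms <- stringr::str_split(dplyr::coalesce(raw$mp_terms, ""), ";")
  terms <- purrr::map(terms, function(x) {
    x <- stringr::str_trim(x)
    x[nzchar(x)]
  })
  ok <- purrr::map(terms, ~ stringr::str_detect(.x, MP_TERM_RE))
  n_bad <- sum(purrr::map_int(ok, ~ sum(!.x)))
  if (n_bad > 0L) {
    warn(sprintf("%s: dropped %d malformed MP term(s) (expected MP: + 7 digits)",
                 source, n_bad))
  }
  records <- tibble(
    symbol = stringr::str_trim(raw$symbol),
    source = source,
    zygosity = raw$zygosity,
    allele_attribute = raw$allele_attribute,
    n_genes_affected = raw$n_genes_affected,
    mp_terms = purrr::map2(terms, ok, ~ .x[.y])
  )
  attr(records, "parse_report") <- list(
    n_rows = nrow(raw),
    n_terms_dropped = n_bad
  )
  records
}

#' Read per-cell-line essentiality calls
#'
#' @param path Path to a long-format TSV with columns `symbol`, `cell_line`,
#'   `study`, `essential`, `tested`.
#' @return A tibble of calls; `essential` implies `tested`.
#' @export
read_essentiality_calls <- function(path) {
  calls <- read_source_tsv(path, readr::cols(
    symbol = readr::col_character(),
    cell_line = readr::col_character(),
    study = readr::col_character(),
    essential = readr::col_logical(),
    tested = readr::col_logical()
  ))
  assert_cols(calls, c("symbol", "cell_line", "study", "essential", "tested"),
              "essentiality call table")
  if (any(calls$essential & !calls$tested, na.rm = TRUE)) {
    abort("essential calls on untested (symbol, cell_line, study) rows",
          class = "devlethal_validation_error")
  }
  mutate(calls, symbol = stringr::str_trim(.data$symbol))
}

#' Read a gene-level constraint score table
#'
#' @param path Path to a TSV with columns `symbol`, `mis_z`, `pLI`
#'   (one pre-collapsed row per gene).
#' @return A tibble of constraint scores.
#' @export
read_constraint_scores <- function(path) {
  scores <- read_source_tsv(path, readr::cols(
    symbol = readr::col_character(),
    mis_z = readr::col_double(),
    pLI = readr::col_double()
  ))
  assert_cols(scores, c("symbol", "mis_z", "pLI"), "constraint score table")
  bad <- !is.na(scores$pLI) & (scores$pLI < 0 | scores$pLI > 1)
  if (any(bad)) {
    abort(sprintf("pLI outside [0, 1] for: %s",
                  paste(scores$symbol[bad], collapse = ", ")),
          class = "devlethal_validation_error")
  }
  dup <- scores$symbol[duplicated(scores$symbol)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicated symbol(s) in constraint table: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "devlethal_validation_error")
  }
  mutate(scores, symbol = stringr::str_trim(.data$symbol))
}

#' Read a one-column gene list (regional-constraint metric membership)
#'
#' @param path Path to a file with one gene symbol per line (optionally a
#'   `symbol` header).
#' @return A character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- stringr::str_trim(x)
  x <- x[nzchar(x) & !stringr::str_starts(x, "#")]
  if (length(x) > 0L && identical(x[[1L]], "symbol")) x <- x[-1L]
  unique(x)
}

GO_NAMESPACES <- c("component", "function", "process")

#' Read a GO-slim annotation table
#'
#' @param path Path to a TSV with columns `symbol`, `go_id`, `namespace`
#'   (namespace one of component/function/process, following GAF-slim
#'   aspect semantics).
#' @return A tibble of annotations with duplicates collapsed.
#' @export
read_go_annotations <- function(path) {
  ann <- read_source_tsv(path, readr::cols(.default = readr::col_character()))
  assert_cols(ann, c("symbol", "go_id", "namespace"), "GO annotation table")
  bad <- unique(ann$namespace[ann$namespace %notin% GO_NAMESPACES])
  if (length(bad) > 0L) {
    abort(sprintf("unknown GO namespace(s): %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(GO_NAMESPACES, collapse = "/")),
          class = "devlethal_format_error")
  }
  distinct(mutate(ann, symbol = stringr::str_trim(.data$symbol)))
}

#' Read a full source bundle from a configuration
#'
#' The configuration maps each source role to a path, either as a named list
#' or as a YAML file with top-level keys `universe`, `genemap`, `mgi`, `impc`,
#' `essentiality`, `constraint`, `regional_gamma`, `regional_ccr`,
#' `regional_nmd`, `go`.
#'
#' @param config A named list of paths or the path of a YAML file.
#' @return A list of parsed source tables (`universe`, `genemap`, `mouse`,
#'   `essentiality`, `constraint`, `regional`, `go`).
#' @export
read_source_bundle <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  roles <- c("universe", "genemap", "mgi", "impc", "essentiality",
             "constraint", "regional_gamma", "regional_ccr", "regional_nmd",
             "go")
  missing <- setdiff(roles, names(config))
  if (length(missing) > 0L) {
    abort(sprintf("source configuration is missing role(s): %s",
                  paste(missing, collapse = ", ")),
          class = "devlethal_format_error")
  }
  list(
    universe = read_gene_universe(config$universe),
    genemap = read_genemap(config$genemap),
    mouse = bind_rows(read_mouse_phenotypes(config$mgi, "MGI"),
                      read_mouse_phenotypes(config$impc, "IMPC")),
    essentiality = read_essentiality_calls(config$essentiality),
    constraint = read_constraint_scores(config$constraint),
    regional = list(gamma = read_gene_list(config$regional_gamma),
                    ccr = read_gene_list(config$regional_ccr),
                    nmd = read_gene_list(config$regional_nmd)),
    go = read_go_annotations(config$go)
  )
}

MASTER_SHEETS <- c(
  all_genes = "master_all_genes.tsv",
  cell_essential_not_mouse_lethal = "master_cell_essential_not_mouse_lethal.tsv",
  candidates = "master_candidate_developmental_lethal.tsv",
  mouse_lethal_outside_filter = "master_mouse_lethal_outside_recessive_filter.tsv"
)

#' Write the integrated master table as a four-sheet TSV bundle
#'
#' Sheet 1 holds every gene in the universe; sheet 2 the cell-essential genes
#' not classified mouse-lethal; sheet 3 the candidate developmental-lethal
#' genes; sheet 4 the genes lethal only outside the recessive-null filter
#' (heterozygous-knockout or non-null routes). A JSON manifest records per
#' sheet row counts.
#'
#' @param master A master table from [build_master()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a named list.
#' @export
write_master_table <- function(master, out_dir) {
  if (nrow(master) == 0L) {
    abort("master table is empty", class = "devlethal_validation_error")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory: %s", out_dir),
                   class = "devlethal_io_error")
  }
  sheets <- list(
    all_genes = master,
    cell_essential_not_mouse_lethal =
      filter(master, .data$essential_agg %in% TRUE &
               !(.data$mouse_lethal %in% TRUE)),
    candidates = filter(master, .data$candidate_dev_lethal %in% TRUE),
    mouse_lethal_outside_filter =
      filter(master, .data$outside_recessive_filter %in% TRUE)
  )
  files <- file.path(out_dir, MASTER_SHEETS[names(sheets)])
  purrr::walk2(sheets, files, ~ readr::write_tsv(.x, .y, progress = FALSE))
  manifest <- list(
    sheets = purrr::imap(sheets, ~ list(file = unname(MASTER_SHEETS[[.y]]),
                                        n_rows = nrow(.x)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

master_col_types <- function() {
  readr::cols(
    symbol = readr::col_character(),
    is_omim_clinical = readr::col_logical(),
    inheritance_class = readr::col_character(),
    lethal_class = readr::col_character(),
    mouse_data = readr::col_logical(),
    mouse_lethal = readr::col_logical(),
    mouse_stage = readr::col_character(),
    outside_recessive_filter = readr::col_logical(),
    premature_death = readr::col_logical(),
    cell_data = readr::col_logical(),
    n_lines_tested = readr::col_integer(),
    n_lines_essential = readr::col_integer(),
    essential_agg = readr::col_logical(),
    essential_all_lines = readr::col_logical(),
    has_scores = readr::col_logical(),
    missense_constrained = readr::col_logical(),
    lof_constrained = readr::col_logical(),
    regional_constrained = readr::col_logical(),
    constraint_category = readr::col_character(),
    candidate_dev_lethal = readr::col_logical()
  )
}

#' Re-read a written master-table bundle
#'
#' Inverse of [write_master_table()]: reading sheet 1 back reproduces the
#' master tibble exactly.
#'
#' @param dir Directory written by [write_master_table()].
#' @return The master tibble.
#' @export
read_master_table <- function(dir) {
  path <- file.path(dir, MASTER_SHEETS[["all_genes"]])
  readr::read_tsv(path, col_types = master_col_types(), progress = FALSE)
}
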