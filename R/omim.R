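#' OMIM-style disease-gene curation
#'
#' Reproduces the curation of clinically relevant Mendelian disease genes from
#' a genemap-style dump: a gene qualifies when it lies in the protein-coding
#' universe and carries at least one phenotype whose molecular basis is known
#' (mapping key 3) that is not a non-disease, not a susceptibility, not
#' provisional, not somatic and not a contiguous-deletion syndrome. Prenatal/
#' infantile lethality is then flagged from free clinical text with a
#' configurable phrase lexicon split into an explicit tier (List A: time of
#' death stated before birth or before three months) and a permissive tier
#' (List B: imprecise infancy wording; a superset of List A).
#'
#' @name omim-curation
NULL

INHERITANCE_PATTERNS <- c(
  "X-linked dominant"   = "XLD",
  "X-linked recessive"  = "XLR",
  "X-linked"            = "XL_unspecified",
  "Autosomal recessive" = "AR",
  "Autosomal dominant"  = "AD",
  "Mitochondrial"       = "MT"
)

parse_inheritance_modes <- function(text) {
  hit <- character(0)
  remaining <- text
  # longest patterns first so "X-linked recessive" is not consumed as "X-linked"
  for (pat in names(INHERITANCE_PATTERNS)) {
    if (stringr::str_detect(remaining, stringr::fixed(pat, ignore_case = TRUE))) {
      hit <- c(hit, INHERITANCE_PATTERNS[[pat]])
      remaining <- stringr::str_remove_all(
        remaining, stringr::fixed(pat, ignore_case = TRUE))
    }
  }
  unname(hit)
}

#' Parse one genemap phenotype string
#'
#' Modifier syntax follows the genemap conventions: square brackets mark a
#' non-disease, braces a susceptibility, a leading `?` a provisional link, a
#' trailing `(n)` the phenotype mapping key (3 = molecular basis known,
#' 4 = contiguous-deletion syndrome). The word "somatic" in the label marks
#' somatic-mutation phenotypes, and inheritance wording after the mapping key
#' is parsed into modes.
#'
#' @param raw A non-empty phenotype string.
#' @return A one-row tibble with the parsed fields; `inheritance_modes` is a
#'   list-column holding a character vector of modes.
#' @export
#' @examples
#' parse_phenotype_string("?Cataract 42 (3)")
#' parse_phenotype_string("{Diabetes, susceptibility to} (3)")
parse_phenotype_string <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  s <- stringr::str_trim(raw)

  key_match <- stringr::str_match(s, "\\((\\d)\\)(?!.*\\(\\d\\))")
  mapping_key <- if (is.na(key_match[1, 2])) 0L else as.integer(key_match[1, 2])
  inheritance_text <- if (!is.na(key_match[1, 1])) {
    stringr::str_sub(s, stringr::str_locate(s, stringr::fixed(key_match[1, 1]))[1, 2] + 1L)
  } else ""

  label <- if (!is.na(key_match[1, 1])) {
    stringr::str_trim(stringr::str_remove(
      stringr::str_sub(s, 1L, stringr::str_locate(s, stringr::fixed(key_match[1, 1]))[1, 1] - 1L),
      ",\\s*$"))
  } else s

  nondisease <- stringr::str_starts(label, "\\[") & stringr::str_detect(label, "\\]")
  susceptibility <- stringr::str_starts(label, "\\{|\\?\\{") &
    stringr::str_detect(label, "\\}")
  core <- stringr::str_remove_all(label, "[\\[\\]{}]")
  provisional <- stringr::str_starts(stringr::str_trim(core), stringr::fixed("?"))
  core <- stringr::str_remove(stringr::str_trim(core), "^\\?")

  tibble(
    label = stringr::str_trim(core),
    mapping_key = mapping_key,
    nondisease = nondisease,
    susceptibility = susceptibility,
    provisional = provisional,
    somatic = stringr::str_detect(core, stringr::regex("\\bsomatic\\b",
                                                       ignore_case = TRUE)),
    contiguous_deletion = mapping_key == 4L,
    inheritance_modes = list(parse_inheritance_modes(inheritance_text))
  )
}

#' Parse all phenotype rows of a genemap table
#'
#' @param genemap A tibble from [read_genemap()].
#' @return The genemap rows with parsed phenotype fields bound on.
#' @export
parse_genemap <- function(genemap) {
  assert_cols(genemap, c("symbol", "phenotype"), "genemap table")
  parsed <- purrr::map(genemap$phenotype, parse_phenotype_string)
  dplyr::bind_cols(
    select(genemap, "symbol", dplyr::any_of("clinical_synopsis")),
    bind_rows(parsed)
  )
}

phenotype_qualifies <- function(parsed) {
  parsed$mapping_key == 3L &
    !parsed$nondisease & !parsed$susceptibility & !parsed$provisional &
    !parsed$somatic & !parsed$contiguous_deletion
}

#' Default prenatal/infantile lethality lexicon
#'
#' The vocabulary actually used for curation is data, not code: this default
#' captures the mechanism (explicit death before birth / before three months
#' for List A; imprecise infancy wording for List B) and can be replaced via
#' [read_lethality_lexicon()]. List A and List B phrase sets are disjoint;
#' at the gene level List A membership implies List B membership.
#'
#' @return A list with elements `listA_terms`, `listB_terms`,
#'   `exclusion_terms` (lower-cased phrases).
#' @export
default_lethality_lexicon <- function() {
  list(
    listA_terms = c(
      "died in utero", "death in utero", "stillbirth", "stillborn",
      "fetal demise", "foetal demise", "hydrops fetalis",
      "death before birth", "neonatal death", "neonatal lethal",
      "died in the neonatal period", "perinatal death",
      "died at 2 weeks", "died at 3 weeks", "died at 6 weeks",
      "died by 8 weeks", "died at 2 months", "died by 3 months",
      "death in the first weeks of life", "lethal before birth"
    ),
    listB_terms = c(
      "death in infancy", "shortly after birth", "early infantile death",
      "died in infancy", "death in early infancy", "infantile lethal",
      "lethal"
    ),
    exclusion_terms = c("sublethal", "lethality in mice")
  )
}

validate_lexicon <- function(lexicon) {
  stopifnot(is.list(lexicon),
            all(c("listA_terms", "listB_terms") %in% names(lexicon)))
  lexicon$listA_terms <- tolower(lexicon$listA_terms)
  lexicon$listB_terms <- tolower(lexicon$listB_terms)
  lexicon$exclusion_terms <- tolower(lexicon$exclusion_terms %||% character(0))
  overlap <- intersect(lexicon$listA_terms, lexicon$listB_terms)
  if (length(overlap) > 0L) {
    abort(sprintf("lexicon List A and List B phrase sets overlap: %s",
                  paste(overlap, collapse = ", ")),
          class = "devlethal_validation_error")
  }
  lexicon
}

#' Load a lethality lexicon from YAML
#'
#' @param path YAML file with keys `listA_terms`, `listB_terms` and optional
#'   `exclusion_terms`.
#' @return A validated lexicon list.
#' @export
read_lethality_lexicon <- function(path) {
  validate_lexicon(yaml::read_yaml(path))
}

normalise_clinical_text <- function(x) {
  stringr::str_squish(tolower(dplyr::coalesce(x, "")))
}

#' Classify clinical free text into lethality tiers
#'
#' Case-insensitive substring matching over whitespace-normalised text:
#' List A phrases (explicit death before birth or before three months) win
#' over List B phrases (imprecise infancy wording); exclusion phrases are
#' masked out of the text before matching so that, e.g., "sublethal" does not
#' trigger the bare "lethal" List B phrase.
#'
#' @param clinical_text Character vector of free-text clinical descriptions.
#' @param lexicon A lexicon list (default [default_lethality_lexicon()]).
#' @return A character vector over `c("listA", "listB", "none")`.
#' @export
#' @examples
#' flag_lethal_phenotypes("fetal demise at 22 weeks gestation")
#' flag_lethal_phenotypes("death in infancy")
flag_lethal_phenotypes <- function(clinical_text,
                                   lexicon = default_lethality_lexicon()) {
  lexicon <- validate_lexicon(lexicon)
  text <- normalise_clinical_text(clinical_text)
  for (ex in lexicon$exclusion_terms) {
    text <- stringr::str_replace_all(text, stringr::fixed(ex), " ")
  }
  match_any <- function(text, phrases) {
    if (length(phrases) == 0L) return(rep(FALSE, length(text)))
    Reduce(`|`, lapply(phrases,
                       function(p) stringr::str_detect(text, stringr::fixed(p))))
  }
  a <- match_any(text, lexicon$listA_terms)
  b <- match_any(text, lexicon$listB_terms)
  dplyr::case_when(a ~ "listA", b ~ "listB", .default = "none")
}

#' Derive the inheritance class of a gene from its phenotype modes
#'
#' The classes are mutually exclusive, so a precedence order is applied:
#' mitochondrial > X-linked > AR/AD (both autosomal modes present) >
#' AD > AR; genes with no recognised mode are `unknown`.
#'
#' @param modes Character vector of inheritance modes (possibly with
#'   duplicates) over AR, AD, XLR, XLD, XL_unspecified, MT, other.
#' @return One of `"AR"`, `"AD"`, `"AR/AD"`, `"XL"`, `"MT"`, `"unknown"`.
#' @export
classify_inheritance <- function(modes) {
  modes <- unique(unlist(modes))
  has_xl <- any(modes %in% c("XLR", "XLD", "XL_unspecified"))
  if ("MT" %in% modes) "MT"
  else if (has_xl) "XL"
  else if (all(c("AR", "AD") %in% modes)) "AR/AD"
  else if ("AD" %in% modes) "AD"
  else if ("AR" %in% modes) "AR"
  else "unknown"
}

#' Curate clinically relevant disease genes from parsed genemap rows
#'
#' A gene is retained iff it is in the protein-coding universe and has at
#' least one qualifying phenotype (see [parse_phenotype_string()] for the
#' per-phenotype exclusions, applied per phenotype: a somatic phenotype does
#' not disqualify a gene that also carries a germline one). The per-gene
#' exclusion reasons for dropped genes are attached as attribute
#' `"exclusion_log"`. Inheritance is classified over qualifying phenotypes
#' only; lethality is flagged from the clinical synopsis text and
#' `lethal_inheritance` carries the modes of the phenotype rows whose text
#' matched.
#'
#' @param parsed Parsed genemap rows from [parse_genemap()].
#' @param universe Universe tibble from [read_gene_universe()] (or a character
#'   vector of symbols).
#' @param lexicon Lethality lexicon.
#' @param overrides Optional tibble (`symbol`, `decision` in
#'   confirm/reject) modelling manual clinical review of the lethality calls:
#'   `reject` forces `lethal_class = "none"`, `confirm` keeps the match.
#' @return A tibble with one row per curated gene: `symbol`,
#'   `inheritance_class`, `lethal_class`, `lethal_inheritance` (list-column),
#'   `n_qualifying`.
#' @export
filter_clinically_relevant <- function(parsed, universe,
                                       lexicon = default_lethality_lexicon(),
                                       overrides = NULL) {
  symbols <- if (is.data.frame(universe)) universe$symbol else universe
  parsed <- mutate(parsed, qualifies = phenotype_qualifies(parsed))

  in_universe <- parsed$symbol %in% symbols
  per_gene <- parsed |>
    group_by(.data$symbol) |>
    summarise(any_qualifying = any(.data$qualifies), .groups = "drop")

  excluded <- parsed |>
    filter(!.data$qualifies | .data$symbol %notin% symbols) |>
    mutate(reason = case_when(
      .data$symbol %notin% symbols ~ "not in protein-coding universe",
      .data$mapping_key == 0L ~ "no mapping key",
      .data$contiguous_deletion ~ "contiguous deletion",
      .data$mapping_key != 3L ~ "molecular basis not known",
      .data$nondisease ~ "nondisease",
      .data$susceptibility ~ "susceptibility",
      .data$provisional ~ "provisional",
      .data$somatic ~ "somatic",
      .default = "other"
    )) |>
    select("symbol", "label", "reason")

  keep <- parsed |>
    filter(.data$qualifies, .data$symbol %in% symbols)

  lethal_flags <- flag_lethal_phenotypes(
    dplyr::coalesce(keep$clinical_synopsis %||% rep(NA_character_, nrow(keep)), ""),
    lexicon)
  keep$row_lethal <- factor(lethal_flags, levels = c("listA", "listB", "none"))

  curated <- keep |>
    group_by(.data$symbol) |>
    summarise(
      inheritance_class = classify_inheritance(.data$inheritance_modes),
      lethal_class = as.character(sort(.data$row_lethal)[1L]),
      lethal_inheritance = list(
        unique(unlist(.data$inheritance_modes[.data$row_lethal != "none"]))),
      n_qualifying = dplyr::n(),
      .groups = "drop"
    )

  if (!is.null(overrides)) {
    assert_cols(overrides, c("symbol", "decision"), "override table")
    reject <- overrides$symbol[overrides$decision == "reject"]
    curated <- mutate(
      curated,
      lethal_class = if_else(.data$symbol %in% reject, "none",
                             .data$lethal_class),
      lethal_inheritance = purrr::map2(
        .data$lethal_inheritance, .data$symbol %in% reject,
        ~ if (.y) character(0) else .x))
  }

  attr(curated, "exclusion_log") <- excluded
  curated
}
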