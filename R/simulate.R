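#' Synthetic source-bundle generator with planted ground truth
#'
#' Emulates the seven source-table dialects the pipeline consumes — gene
#' universe, genemap-style disease phenotypes, MGI- and IMPC-style mouse
#' knockout reports, per-cell-line essentiality calls, gnomAD-style constraint
#' scores with three regional-constraint lists, and a GO-slim annotation
#' table — from a single configuration, planting a per-gene ground truth for
#' every downstream classification. A single root seed drives independent
#' per-source substreams so adding a source does not reshuffle the others.
#'
#' @name synthetic-data
NULL

CELL_LINE_STUDIES <- list(
  study1 = c("HAP1", "KBM7"),
  study2 = c("KBM7", "K562", "JIYOYE", "RAJI"),
  study3 = c("HCT116", "HELA", "GBM", "RPE1", "DLD1", "HEK293")
)
CELL_LINES <- unique(unlist(CELL_LINE_STUDIES))  # 11 distinct lines

BENIGN_MP_TERMS <- c("MP:0001392", "MP:0002066", "MP:0005386", "MP:0003631",
                     "MP:0005378")

default_constraint_rates <- function() {
  # whole-gene flag probabilities per inheritance class, set from the
  # stratified missense / LoF proportions reported for disease genes, with a
  # lower non-disease base rate; regional constraint planted independently.
  tibble(
    class       = c("AR",  "AD",   "AR/AD", "XL",   "MT",  "nondisease"),
    p_missense  = c(0.028, 0.238,  0.12,    0.22,   0.0,   0.06),
    p_lof       = c(0.061, 0.453,  0.25,    0.698,  0.027, 0.12),
    p_regional  = c(0.10,  0.15,   0.12,    0.15,   0.05,  0.08)
  )
}

#' Build a simulation configuration
#'
#' Defaults describe a mid-sized universe with the marginal structure of the
#' real sources: the disease-gene fraction, lethal-given-disease fraction and
#' List A share mirror the curated catalogue; mouse lethality follows a
#' logistic model in disease status, human lethality tier and whole-gene
#' constraint; cell essentiality is coupled to the latent mouse-lethality
#' flag so the essentialome is largely a subset of the mouse-lethal set.
#'
#' @param n_genes Number of protein-coding universe genes.
#' @param n_noncoding Extra non-protein-coding decoy rows in the universe file.
#' @param frac_disease Fraction of universe genes planted as clinically
#'   relevant disease genes.
#' @param frac_lethal_given_disease Fraction of disease genes planted with a
#'   prenatal/infantile-lethal phenotype (List B).
#' @param frac_listA_given_lethal Fraction of lethal genes in the explicit
#'   List A tier.
#' @param inheritance_mix Probability vector over AR, AD, AR/AD, XL, MT.
#' @param frac_decoy_phenotypes Fraction of non-disease genes given only
#'   non-qualifying phenotype rows (susceptibility, non-disease, provisional,
#'   somatic, contiguous-deletion or unmapped).
#' @param mouse_lethal_coef Named vector `intercept`, `disease`, `lethal`,
#'   `constrained`: logit-scale coefficients of the planted mouse-lethality
#'   model.
#' @param mouse_missingness Probability a gene has no mouse knockout data.
#' @param mouse_both_sources Probability a gene with mouse data is covered by
#'   both MGI and IMPC (the remainder splits evenly between single sources).
#' @param mouse_source_discordance Probability the IMPC lethality call of a
#'   both-source gene disagrees with the MGI call.
#' @param frac_het_lethal Fraction of mouse-data genes planted lethal only
#'   through a heterozygous knockout (outside the recessive-null filter).
#' @param stage_mix Probability vector over the lethality stages for lethal
#'   genes.
#' @param frac_premature_death Probability a mouse-data gene carries the
#'   premature-death term.
#' @param frac_mouse_decoy_rows Fraction of mouse-data genes given an extra
#'   ineligible record (multi-gene or non-null allele) carrying a lethal term.
#' @param cell_essential_given_mouse_lethal,cell_essential_given_not
#'   Probability the latent cell-essential flag is set, conditional on the
#'   latent mouse-lethality flag.
#' @param cell_missingness Per-study probability a gene is untested.
#' @param essentiality_noise Per-(line, study) probability an essentiality
#'   call is flipped.
#' @param constraint_rates Tibble of per-class whole-gene/regional constraint
#'   probabilities (see `devlethal:::default_constraint_rates`).
#' @param constraint_missingness Probability a gene is absent from the
#'   constraint score table.
#' @param go_n_terms Named vector: number of GO-slim terms per namespace.
#' @param go_n_skew Number of process terms skewed toward each of the
#'   dominant and recessive disease-gene families.
#' @param go_base_rate_range Range of per-term baseline annotation
#'   probabilities.
#' @param go_skew_high,go_skew_low Annotation probabilities of a skewed term
#'   in the favoured and disfavoured family.
#' @param seed Root seed (integer) for the per-source substreams.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_noncoding = max(10L, round(n_genes * 0.01)),
                       frac_disease = 3187 / 19196,
                       frac_lethal_given_disease = 624 / 3187,
                       frac_listA_given_lethal = 344 / 624,
                       inheritance_mix = c(AR = 0.58, AD = 0.25,
                                           "AR/AD" = 0.05, XL = 0.10,
                                           MT = 0.02),
                       frac_decoy_phenotypes = 0.05,
                       mouse_lethal_coef = c(
                         intercept = qlogis(0.27),
                         disease = qlogis(0.50) - qlogis(0.27),
                         lethal = qlogis(0.75) - qlogis(0.50),
                         constrained = qlogis(0.58) - qlogis(0.27)),
                       mouse_missingness = 1 - 9397 / 19196,
                       mouse_both_sources = 1290 / 9397,
                       mouse_source_discordance = 0.16,
                       frac_het_lethal = 0.02,
                       stage_mix = c(embryonic = 0.40, prenatal = 0.15,
                                     perinatal = 0.15,
                                     preweaning_postnatal = 0.30),
                       frac_premature_death = 0.03,
                       frac_mouse_decoy_rows = 0.05,
                       cell_essential_given_mouse_lethal = 0.34,
                       cell_essential_given_not = 0.008,
                       cell_missingness = 1 - (15903 / 19196)^(1 / 3),
                       essentiality_noise = 0,
                       constraint_rates = default_constraint_rates(),
                       constraint_missingness = 72 / 3187,
                       go_n_terms = c(component = 15, "function" = 20,
                                      process = 30),
                       go_n_skew = 5,
                       go_base_rate_range = c(0.02, 0.10),
                       go_skew_high = 0.40,
                       go_skew_low = 0.02,
                       seed = 1L) {
  config <- list(
    n_genes = as.integer(n_genes), n_noncoding = as.integer(n_noncoding),
    frac_disease = frac_disease,
    frac_lethal_given_disease = frac_lethal_given_disease,
    frac_listA_given_lethal = frac_listA_given_lethal,
    inheritance_mix = inheritance_mix,
    frac_decoy_phenotypes = frac_decoy_phenotypes,
    mouse_lethal_coef = mouse_lethal_coef,
    mouse_missingness = mouse_missingness,
    mouse_both_sources = mouse_both_sources,
    mouse_source_discordance = mouse_source_discordance,
    frac_het_lethal = frac_het_lethal,
    stage_mix = stage_mix,
    frac_premature_death = frac_premature_death,
    frac_mouse_decoy_rows = frac_mouse_decoy_rows,
    cell_essential_given_mouse_lethal = cell_essential_given_mouse_lethal,
    cell_essential_given_not = cell_essential_given_not,
    cell_missingness = cell_missingness,
    essentiality_noise = essentiality_noise,
    constraint_rates = constraint_rates,
    constraint_missingness = constraint_missingness,
    go_n_terms = go_n_terms, go_n_skew = as.integer(go_n_skew),
    go_base_rate_range = go_base_rate_range,
    go_skew_high = go_skew_high, go_skew_low = go_skew_low,
    seed = as.integer(seed)
  )
  validate_sim_config(config)
}

validate_sim_config <- function(config) {
  probs <- c(config$frac_disease, config$frac_lethal_given_disease,
             config$frac_listA_given_lethal, config$frac_decoy_phenotypes,
             config$mouse_missingness, config$mouse_both_sources,
             config$mouse_source_discordance, config$frac_het_lethal,
             config$frac_premature_death, config$frac_mouse_decoy_rows,
             config$cell_essential_given_mouse_lethal,
             config$cell_essential_given_not, config$cell_missingness,
             config$essentiality_noise, config$constraint_missingness,
             config$inheritance_mix, config$stage_mix,
             config$go_base_rate_range, config$go_skew_high,
             config$go_skew_low)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all simulation probabilities must lie in [0, 1]",
          class = "devlethal_config_error")
  }
  for (vec in list(config$inheritance_mix, config$stage_mix)) {
    if (abs(sum(vec) - 1) > 1e-9) {
      abort("probability vectors must sum to 1 (within 1e-9)",
            class = "devlethal_config_error")
    }
  }
  if (config$n_genes < 10L) {
    abort("n_genes must be at least 10", class = "devlethal_config_error")
  }
  rates <- config$constraint_rates
  assert_cols(rates, c("class", "p_missense", "p_lof", "p_regional"),
              "constraint_rates")
  structure(config, class = "sim_config")
}

#' Configuration preset matching the full catalogue scale
#'
#' A [sim_config()] whose expected marginal counts reproduce the documented
#' full-scale structure: 19,196 protein-coding genes, an expected 3187
#' disease genes of which 624 carry a prenatal/infantile-lethal phenotype
#' (344 in List A), a 39.2% pre-weaning lethality rate among the roughly
#' 9397 genes with recessive knockout data, an essentialome of about 14% of
#' the genes tested by all three studies, and 84% cross-source lethality
#' concurrence.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
paper_scale_config <- function(...) {
  sim_config(n_genes = 19196L, ...)
}

#' Expected marginal counts implied by a configuration
#'
#' @param config A `"sim_config"` object.
#' @return A named list of expected counts (disease genes, lethal genes,
#'   List A genes, mouse-data genes).
#' @export
expected_counts <- function(config) {
  n_disease <- config$n_genes * config$frac_disease
  n_lethal <- n_disease * config$frac_lethal_given_disease
  list(
    n_disease = n_disease,
    n_lethal = n_lethal,
    n_listA = n_lethal * config$frac_listA_given_lethal,
    n_mouse_data = config$n_genes * (1 - config$mouse_missingness)
  )
}

rbern <- function(n, p) runif(n) < p

sample_vec <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

# ---- skeleton: gene-level latent truth ------------------------------------

simulate_skeleton <- function(config) {
  n <- config$n_genes
  genes <- tibble(
    symbol = sprintf("GENE%05d", seq_len(n)),
    gene_id = sprintf("ID:%06d", seq_len(n))
  )

  genes$is_disease <- rbern(n, config$frac_disease)
  classes <- names(config$inheritance_mix)
  genes$inheritance_class <- if_else(
    genes$is_disease,
    sample_vec(classes, n, prob = config$inheritance_mix),
    NA_character_)
  genes$chromosome <- if_else(
    !is.na(genes$inheritance_class) & genes$inheritance_class == "XL",
    "X", as.character(sample.int(22L, n, replace = TRUE)))

  lethal <- genes$is_disease & rbern(n, config$frac_lethal_given_disease)
  lista <- lethal & rbern(n, config$frac_listA_given_lethal)
  genes$lethal_class <- case_when(lista ~ "listA", lethal ~ "listB",
                                  genes$is_disease ~ "none",
                                  .default = NA_character_)

  # whole-gene / regional constraint flags, class-conditional
  rates <- config$constraint_rates
  class_key <- if_else(genes$is_disease, genes$inheritance_class, "nondisease")
  idx <- match(class_key, rates$class)
  idx[is.na(idx)] <- match("nondisease", rates$class)
  genes$missense_constrained <- rbern(n, rates$p_missense[idx])
  genes$lof_constrained <- rbern(n, rates$p_lof[idx])
  genes$regional_constrained <- rbern(n, rates$p_regional[idx])

  # latent mouse lethality (logistic in disease status, human lethality tier,
  # whole-gene constraint); realised for every gene, observed only where
  # mouse data exists
  coef <- config$mouse_lethal_coef
  eta <- coef[["intercept"]] +
    coef[["disease"]] * genes$is_disease +
    coef[["lethal"]] * (genes$lethal_class %in% c("listA", "listB")) +
    coef[["constrained"]] * (genes$missense_constrained | genes$lof_constrained)
  genes$latent_mouse_lethal <- rbern(n, plogis(eta))
  genes$latent_stage <- if_else(
    genes$latent_mouse_lethal,
    sample_vec(names(config$stage_mix), n, prob = config$stage_mix),
    "none")

  p_ess <- if_else(genes$latent_mouse_lethal,
                   config$cell_essential_given_mouse_lethal,
                   config$cell_essential_given_not)
  genes$latent_cell_essential <- rbern(n, p_ess)
  genes
}

# ---- per-source realisations ----------------------------------------------

simulate_universe_table <- function(genes, config) {
  n_extra <- config$n_noncoding
  extra <- tibble(
    symbol = sprintf("PSEUDO%04d", seq_len(n_extra)),
    gene_id = sprintf("ID:P%05d", seq_len(n_extra)),
    locus_type = sample_vec(c("pseudogene", "lncRNA", "other"), n_extra),
    chromosome = as.character(sample.int(22L, n_extra, replace = TRUE))
  )
  coding <- mutate(select(genes, "symbol", "gene_id", "chromosome"),
                   locus_type = "protein-coding")
  rows <- bind_rows(coding, extra)
  rows[sample.int(nrow(rows)), c("symbol", "gene_id", "locus_type",
                                 "chromosome")]
}

LETHAL_FILLER <- c(
  "Affected individuals presented with severe hypotonia and feeding difficulty;",
  "Two sibships showed multiple congenital anomalies;",
  "The reported pregnancies were complicated by polyhydramnios;",
  "Biallelic variants were reported in consanguineous families;")
NONLETHAL_SYNOPSIS <- c(
  "Adult-onset progressive ataxia with normal lifespan.",
  "Slowly progressive proximal weakness beginning in adolescence.",
  "Isolated sensorineural hearing impairment with onset in childhood.",
  "Mild intellectual disability with survival into adulthood.")

inheritance_text_of <- function(class, xl_dominant) {
  dplyr::case_match(class,
    "AR" ~ "Autosomal recessive",
    "AD" ~ "Autosomal dominant",
    "AR/AD" ~ "Autosomal recessive, Autosomal dominant",
    "XL" ~ if_else(xl_dominant, "X-linked dominant", "X-linked recessive"),
    "MT" ~ "Mitochondrial")
}

simulate_genemap_table <- function(genes, config, lexicon) {
  disease <- filter(genes, .data$is_disease)
  nd <- nrow(disease)
  lista_pool <- lexicon$listA_terms
  # the bare "lethal" List B phrase is planted with padding that cannot
  # accidentally assemble a List A phrase from the filler text
  listb_pool <- setdiff(lexicon$listB_terms, "lethal")

  synopsis <- character(nd)
  is_lethal <- disease$lethal_class %in% c("listA", "listB")
  phrase <- character(nd)
  phrase[disease$lethal_class == "listA"] <-
    sample_vec(lista_pool, sum(disease$lethal_class == "listA"))
  phrase[disease$lethal_class == "listB"] <-
    sample_vec(listb_pool, sum(disease$lethal_class == "listB"))
  synopsis[is_lethal] <- paste(
    sample_vec(LETHAL_FILLER, sum(is_lethal)), phrase[is_lethal],
    "was reported.")
  synopsis[!is_lethal] <- sample_vec(NONLETHAL_SYNOPSIS, sum(!is_lethal))

  pheno <- sprintf(
    "%s-related disorder %d (3), %s",
    disease$symbol, seq_len(nd),
    inheritance_text_of(disease$inheritance_class, rbern(nd, 0.5)))
  rows <- tibble(symbol = disease$symbol, phenotype = pheno,
                 clinical_synopsis = synopsis)

  # some disease genes carry an extra non-qualifying phenotype row: the
  # per-phenotype exclusion must not disqualify the gene
  extra_idx <- which(rbern(nd, 0.10))
  if (length(extra_idx) > 0L) {
    rows <- bind_rows(rows, tibble(
      symbol = disease$symbol[extra_idx],
      phenotype = sprintf("Carcinoma, somatic %d (3)", extra_idx),
      clinical_synopsis = NA_character_))
  }

  # decoy genes with only non-qualifying rows must never be curated
  nondisease <- filter(genes, !.data$is_disease)
  decoy <- nondisease[rbern(nrow(nondisease), config$frac_decoy_phenotypes), ]
  if (nrow(decoy) > 0L) {
    kinds <- sample.int(5L, nrow(decoy), replace = TRUE)
    decoy_pheno <- dplyr::case_match(
      kinds,
      1L ~ sprintf("{%s trait, susceptibility to} (3)", decoy$symbol),
      2L ~ sprintf("[%s blood group variant] (3)", decoy$symbol),
      3L ~ sprintf("?%s-associated disorder (3)", decoy$symbol),
      4L ~ sprintf("%s deletion syndrome (4)", decoy$symbol),
      5L ~ sprintf("%s-linked trait (1)", decoy$symbol))
    rows <- bind_rows(rows, tibble(
      symbol = decoy$symbol, phenotype = decoy_pheno,
      clinical_synopsis = sample_vec(NONLETHAL_SYNOPSIS, nrow(decoy))))
  }
  arrange(rows, .data$symbol, .data$phenotype)
}

simulate_mouse_tables <- function(genes, config, terms) {
  n <- nrow(genes)
  stages <- names(config$stage_mix)
  has_data <- rbern(n, 1 - config$mouse_missingness)
  both <- has_data & rbern(n, config$mouse_both_sources)
  single_mgi <- has_data & !both & rbern(n, 0.5)
  in_mgi <- both | single_mgi
  in_impc <- both | (has_data & !both & !single_mgi)

  l_mgi <- genes$latent_mouse_lethal
  flip <- rbern(n, config$mouse_source_discordance)
  l_impc <- if_else(both, xor(genes$latent_mouse_lethal, flip),
                    genes$latent_mouse_lethal)

  # every potentially-lethal gene gets a planted stage (the latent one, or a
  # fresh draw for lethality introduced by a source flip)
  stage <- genes$latent_stage
  need_stage <- (l_impc | l_mgi) & stage == "none"
  stage[need_stage] <- sample_vec(stages, sum(need_stage),
                                  prob = config$stage_mix)

  observed_lethal <- rep(NA, n)
  observed_lethal[has_data] <- ((l_mgi & in_mgi) | (l_impc & in_impc))[has_data]

  # genes lethal only through a heterozygous knockout
  het_lethal <- has_data & !(observed_lethal %in% TRUE) &
    rbern(n, config$frac_het_lethal)
  het_stage <- rep(NA_character_, n)
  het_stage[het_lethal] <- sample_vec(stages, sum(het_lethal),
                                      prob = config$stage_mix)
  premature <- has_data & rbern(n, config$frac_premature_death)

  term_for_stage <- function(stage) {
    purrr::map_chr(stage, ~ sample_vec(terms$lethal_terms[[.x]], 1L))
  }
  pick_terms <- function(lethal, stage, prem) {
    t <- vector("list", length(lethal))
    t[!lethal] <- purrr::map(seq_len(sum(!lethal)),
                             ~ sample_vec(BENIGN_MP_TERMS, 1L))
    t[lethal] <- as.list(term_for_stage(stage[lethal]))
    t[prem] <- purrr::map(t[prem], ~ c(.x, terms$premature_death_terms[[1L]]))
    t
  }

  build_rows <- function(idx, lethal, source) {
    g <- genes[idx, ]
    rows <- tibble(
      symbol = g$symbol,
      allele_attribute = sample_vec(c("null_knockout", "hypomorph"),
                                    length(idx), prob = c(0.9, 0.1)),
      n_genes_affected = 1L,
      zygosity = "hom",
      mp_terms = pick_terms(lethal[idx], stage[idx], premature[idx])
    )
    het_idx <- which(het_lethal[idx])
    if (length(het_idx) > 0L) {
      rows <- bind_rows(rows, tibble(
        symbol = g$symbol[het_idx],
        allele_attribute = "null_knockout",
        n_genes_affected = 1L,
        zygosity = "het",
        mp_terms = as.list(term_for_stage(het_stage[idx][het_idx]))))
    }
    # multi-gene decoys: lethal terms on alleles affecting two genes are
    # ignored by the classifier entirely
    decoy_idx <- which(rbern(length(idx), config$frac_mouse_decoy_rows))
    if (length(decoy_idx) > 0L) {
      rows <- bind_rows(rows, tibble(
        symbol = g$symbol[decoy_idx],
        allele_attribute = sample_vec(c("other", "null_knockout"),
                                      length(decoy_idx)),
        n_genes_affected = 2L,
        zygosity = "hom",
        mp_terms = as.list(term_for_stage(
          sample_vec(stages, length(decoy_idx), prob = config$stage_mix)))))
    }
    rows$source <- source
    rows
  }

  mgi <- build_rows(which(in_mgi), l_mgi, "MGI")
  impc <- build_rows(which(in_impc), l_impc, "IMPC")

  truth <- tibble(
    symbol = genes$symbol,
    mouse_data = has_data,
    mouse_lethal = observed_lethal,
    mouse_stage = case_when(
      !has_data ~ NA_character_,
      observed_lethal ~ stage,
      het_lethal ~ het_stage,
      .default = "none"),
    outside_recessive_filter = if_else(has_data, het_lethal, NA),
    premature_death = if_else(has_data, premature, NA)
  )
  list(mgi = mgi, impc = impc, truth = truth,
       planted = list(concordance = if (any(both)) {
                        mean((l_mgi == l_impc)[both])
                      } else NA_real_,
                      n_shared = sum(both)))
}

simulate_cell_table <- function(genes, config) {
  n <- nrow(genes)
  n_lines <- length(CELL_LINES)
  essential <- genes$latent_cell_essential
  n_ess <- integer(n)
  n_ess[essential] <- sample_vec(3:11, sum(essential),
                                 prob = c(30, 22, 16, 11, 8, 6, 4, 2, 1))
  n_ess[!essential] <- sample_vec(0:2, sum(!essential),
                                  prob = c(0.75, 0.17, 0.08))
  # planted per-line essentiality membership: n x 11 logical matrix with
  # n_ess[i] randomly placed TRUEs in row i
  ranks <- matrix(runif(n * n_lines), n, n_lines)
  ord <- t(apply(ranks, 1L, rank))
  member <- ord <= n_ess   # recycles n_ess down columns of the n x 11 matrix
  dimnames(member) <- list(NULL, CELL_LINES)

  tested <- matrix(rbern(n * 3L, 1 - config$cell_missingness), nrow = n)
  colnames(tested) <- names(CELL_LINE_STUDIES)

  pairs <- tidyr::crossing(study = names(CELL_LINE_STUDIES),
                           cell_line = CELL_LINES) |>
    filter(purrr::map2_lgl(.data$study, .data$cell_line,
                           ~ .y %in% CELL_LINE_STUDIES[[.x]]))
  calls <- purrr::pmap_dfr(pairs, function(study, cell_line) {
    t_j <- tested[, study]
    noisy <- xor(member[, cell_line], rbern(n, config$essentiality_noise))
    tibble(symbol = genes$symbol, cell_line = cell_line, study = study,
           essential = noisy & t_j, tested = t_j)
  })

  # line coverage: a line is covered when at least one study screening it
  # tested the gene
  covered <- matrix(FALSE, n, n_lines, dimnames = list(NULL, CELL_LINES))
  for (study in names(CELL_LINE_STUDIES)) {
    lines <- CELL_LINE_STUDIES[[study]]
    covered[, lines] <- covered[, lines] | tested[, study]
  }
  n_lines_tested <- rowSums(covered)
  n_lines_essential <- rowSums(covered & member)
  # downstream flags are defined on the universe tested by every study, so
  # partially screened genes carry no-data markers in the truth table too
  all_tested <- rowSums(tested) == 3L
  truth <- tibble(
    symbol = genes$symbol,
    cell_data = all_tested,
    n_lines_tested = if_else(all_tested, as.integer(n_lines_tested),
                             NA_integer_),
    n_lines_essential = if_else(all_tested, as.integer(n_lines_essential),
                                NA_integer_),
    essential_agg = if_else(all_tested, n_lines_essential >= 3L, NA),
    essential_all_lines = if_else(all_tested,
                                  n_lines_tested == n_lines &
                                    n_lines_essential == n_lines, NA)
  )
  list(calls = arrange(calls, .data$symbol, .data$study, .data$cell_line),
       truth = truth)
}

# truncated-normal draws via inverse CDF, so planted constraint flags are
# recovered exactly from the threshold rule
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

simulate_constraint_tables <- function(genes, config) {
  n <- nrow(genes)
  has_scores <- rbern(n, 1 - config$constraint_missingness)
  mis_z <- if_else(genes$missense_constrained,
                   rtrunc_norm(n, 4, 0.5, lower = 3.09),
                   rtrunc_norm(n, 0, 1, upper = 3.09 - 1e-9))
  pli <- if_else(genes$lof_constrained, runif(n, 0.95, 1), runif(n, 0, 0.5))
  scores <- tibble(symbol = genes$symbol, mis_z = round(mis_z, 6),
                   pLI = round(pli, 6))[has_scores, ]

  regional <- genes$symbol[genes$regional_constrained]
  member <- matrix(rbern(length(regional) * 3L, 0.5), ncol = 3L)
  none <- rowSums(member) == 0L
  member[cbind(which(none), sample.int(3L, sum(none), replace = TRUE))] <- TRUE
  truth <- tibble(
    symbol = genes$symbol,
    has_scores = has_scores,
    missense_constrained = if_else(has_scores, genes$missense_constrained, NA),
    lof_constrained = if_else(has_scores, genes$lof_constrained, NA),
    regional_constrained = genes$regional_constrained,
    constraint_category = case_when(
      !has_scores ~ "no_data",
      genes$missense_constrained | genes$lof_constrained ~ "whole_gene",
      genes$regional_constrained ~ "regional_only",
      .default = "none")
  )
  list(scores = scores,
       regional = list(gamma = regional[member[, 1L]],
                       ccr = regional[member[, 2L]],
                       nmd = regional[member[, 3L]]),
       truth = truth)
}

simulate_go_table <- function(genes, config) {
  n <- nrow(genes)
  ns_terms <- purrr::imap(config$go_n_terms, function(k, ns) {
    offset <- switch(ns, component = 1e6, "function" = 2e6, process = 3e6)
    sprintf("GO:%07d", offset + seq_len(k))
  })
  dominant <- genes$is_disease & genes$inheritance_class %in% c("AD", "XL")
  recessive <- genes$is_disease & genes$inheritance_class == "AR"

  k_skew <- config$go_n_skew
  proc <- ns_terms$process
  skew_a <- proc[seq_len(k_skew)]                       # dominant-favoured
  skew_b <- proc[k_skew + seq_len(k_skew)]              # recessive-favoured

  rows <- purrr::imap_dfr(ns_terms, function(terms, ns) {
    purrr::map_dfr(terms, function(term) {
      base <- runif(1, config$go_base_rate_range[1], config$go_base_rate_range[2])
      p <- rep(base, n)
      if (term %in% skew_a) {
        p[dominant] <- config$go_skew_high
        p[recessive] <- config$go_skew_low
      } else if (term %in% skew_b) {
        p[recessive] <- config$go_skew_high
        p[dominant] <- config$go_skew_low
      }
      hit <- rbern(n, p)
      tibble(symbol = genes$symbol[hit], go_id = term, namespace = ns)
    })
  })
  list(annotations = arrange(rows, .data$symbol, .data$go_id),
       planted = list(dominant_terms = skew_a, recessive_terms = skew_b))
}

# ---- driver ----------------------------------------------------------------

#' Generate a synthetic source bundle with planted truth
#'
#' Deterministic for a fixed configuration seed: running twice produces
#' identical tables (and byte-identical files when `dir` is given).
#'
#' @param config A `"sim_config"` object.
#' @param dir Optional output directory; when given, the source files, the
#'   truth table, a `sources.yaml` role-to-path map (consumable by
#'   [read_source_bundle()]) and a `planted.json` summary are written there.
#' @param lexicon Lethality lexicon used for planted clinical text (defaults
#'   to the shipped lexicon so curation recall is exactly 1 at zero noise).
#' @param terms Lethal MP term set used for planted mouse phenotypes.
#' @param sources Which source tables to realise (replicate studies of one
#'   statistic can skip the others); the gene-level skeleton is always drawn,
#'   and each source consumes its own substream, so subsetting never
#'   reshuffles the sources that are kept.
#' @return A list with `bundle` (tibbles: `universe`, `genemap`, `mgi`,
#'   `impc`, `essentiality`, `constraint`, `regional`, `go`), `truth` (one
#'   row per gene, every downstream flag), `planted` (realised cross-source
#'   concordance, skewed GO terms) and `files` (named paths, when `dir` is
#'   given).
#' @export
generate_sources <- function(config, dir = NULL,
                             lexicon = default_lethality_lexicon(),
                             terms = default_lethal_terms(),
                             sources = c("universe", "genemap", "mouse",
                                         "cells", "constraint", "go")) {
  stopifnot(inherits(config, "sim_config"))
  sources <- match.arg(sources, several.ok = TRUE)
  lexicon <- validate_lexicon(lexicon)
  terms <- validate_lethal_terms(terms)

  genes <- with_seed(substream_seed(config$seed, 1L),
                     simulate_skeleton(config))
  universe <- if ("universe" %in% sources) {
    with_seed(substream_seed(config$seed, 2L),
              simulate_universe_table(genes, config))
  }
  genemap <- if ("genemap" %in% sources) {
    with_seed(substream_seed(config$seed, 3L),
              simulate_genemap_table(genes, config, lexicon))
  }
  mouse <- if ("mouse" %in% sources) {
    with_seed(substream_seed(config$seed, 4L),
              simulate_mouse_tables(genes, config, terms))
  }
  cells <- if ("cells" %in% sources) {
    with_seed(substream_seed(config$seed, 5L),
              simulate_cell_table(genes, config))
  }
  constraint <- if ("constraint" %in% sources) {
    with_seed(substream_seed(config$seed, 6L),
              simulate_constraint_tables(genes, config))
  }
  go <- if ("go" %in% sources) {
    with_seed(substream_seed(config$seed, 7L),
              simulate_go_table(genes, config))
  }

  truth <- tibble(
    symbol = genes$symbol,
    is_disease = genes$is_disease,
    inheritance_class = genes$inheritance_class,
    lethal_class = genes$lethal_class
  )
  if (!is.null(mouse)) truth <- left_join(truth, mouse$truth, by = "symbol")
  if (!is.null(cells)) truth <- left_join(truth, cells$truth, by = "symbol")
  if (!is.null(constraint)) {
    truth <- left_join(truth, constraint$truth, by = "symbol")
  }
  if (!is.null(mouse) || !is.null(cells)) {
    mouse_flag <- if (is.null(mouse)) FALSE else {
      dplyr::coalesce(truth$mouse_lethal, FALSE)
    }
    cell_flag <- if (is.null(cells)) FALSE else {
      dplyr::coalesce(truth$essential_agg, FALSE)
    }
    truth$candidate <- (mouse_flag | cell_flag) & !truth$is_disease
  }

  planted <- c(if (!is.null(mouse)) mouse$planted,
               if (!is.null(go)) go$planted)

  bundle <- list(
    universe = universe,
    genemap = genemap,
    mgi = mouse$mgi,
    impc = mouse$impc,
    essentiality = cells$calls,
    constraint = constraint$scores,
    regional = constraint$regional,
    go = go$annotations
  )

  files <- NULL
  if (!is.null(dir)) {
    if (any(purrr::map_lgl(bundle, is.null))) {
      abort("writing a bundle to disk requires all sources to be generated",
            class = "devlethal_config_error")
    }
    files <- write_bundle(bundle, truth, planted, dir)
  }
  list(bundle = bundle, truth = truth, planted = planted, files = files)
}

write_bundle <- function(bundle, truth, planted, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(bundle$universe, p("universe.tsv"), progress = FALSE)
  readr::write_tsv(bundle$genemap, p("genemap.tsv"), progress = FALSE)
  flatten_mouse <- function(tbl) {
    mutate(tbl, mp_terms = purrr::map_chr(.data$mp_terms, paste,
                                          collapse = ";")) |>
      select("symbol", "allele_attribute", "n_genes_affected", "zygosity",
             "mp_terms")
  }
  readr::write_tsv(flatten_mouse(bundle$mgi), p("mgi.tsv"), progress = FALSE)
  readr::write_tsv(flatten_mouse(bundle$impc), p("impc.tsv"), progress = FALSE)
  readr::write_tsv(bundle$essentiality, p("essentiality.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$constraint, p("constraint.tsv"), progress = FALSE)
  readr::write_lines(c("symbol", bundle$regional$gamma),
                     p("regional_gamma.txt"))
  readr::write_lines(c("symbol", bundle$regional$ccr), p("regional_ccr.txt"))
  readr::write_lines(c("symbol", bundle$regional$nmd), p("regional_nmd.txt"))
  readr::write_tsv(bundle$go, p("go_annotations.tsv"), progress = FALSE)
  readr::write_tsv(truth, p("truth.tsv"), progress = FALSE)
  roles <- list(universe = p("universe.tsv"), genemap = p("genemap.tsv"),
                mgi = p("mgi.tsv"), impc = p("impc.tsv"),
                essentiality = p("essentiality.tsv"),
                constraint = p("constraint.tsv"),
                regional_gamma = p("regional_gamma.txt"),
                regional_ccr = p("regional_ccr.txt"),
                regional_nmd = p("regional_nmd.txt"),
                go = p("go_annotations.tsv"))
  yaml::write_yaml(roles, p("sources.yaml"))
  jsonlite::write_json(planted, p("planted.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  c(roles, truth = p("truth.tsv"), sources = p("sources.yaml"),
    planted = p("planted.json"))
}
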