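#' Association statistics for gene-set cross-tabulations
#'
#' Two-sided Fisher exact tests on 2x2 tables, sample odds ratios with Woolf
#' (log-OR) 95% confidence intervals, inheritance-stratified constraint
#' proportions, and hypergeometric GO-slim enrichment with Benjamini-Hochberg
#' FDR control.
#'
#' @name stats-module
NULL

as_2x2 <- function(t) {
  if (is.data.frame(t)) t <- as.matrix(t)
  if (is.matrix(t)) {
    stopifnot(identical(dim(t), c(2L, 2L)))
    t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  }
  stopifnot(length(t) == 4L, all(!is.na(t)), all(t >= 0),
            all(t == round(t)))
  if (sum(t) == 0) {
    abort("empty 2x2 table", class = "devlethal_parameter_error")
  }
  as.double(t)
}

#' Build a 2x2 contingency table from two logical columns
#'
#' Rows are `exposure` (TRUE row first), columns `outcome` (TRUE column
#' first); rows where either flag is `NA` (no data) are dropped.
#'
#' @param df A data frame (e.g. a master table).
#' @param exposure,outcome Column names (tidy-eval) of logical flags.
#' @return A 2x2 integer matrix.
#' @export
contingency_2x2 <- function(df, exposure, outcome) {
  e <- rlang::eval_tidy(rlang::enquo(exposure), data = df)
  o <- rlang::eval_tidy(rlang::enquo(outcome), data = df)
  keep <- !is.na(e) & !is.na(o)
  e <- e[keep]; o <- o[keep]
  matrix(c(sum(e & o), sum(e & !o), sum(!e & o), sum(!e & !o)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(exposure = c("TRUE", "FALSE"),
                         outcome = c("TRUE", "FALSE")))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Sums the hypergeometric probabilities, over all tables with the observed
#' margins, of every table at most as probable as the observed one; ties are
#' resolved with a relative tolerance of 1e-7 on the point probability.
#'
#' @param t A 2x2 matrix/table, or a length-4 vector `c(a, b, c, d)` read
#'   row-wise.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_two_sided(c(5, 5, 5, 5))   # symmetric table: p = 1
fisher_two_sided <- function(t) {
  t <- as_2x2(t)
  a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
  m <- a + b          # row-1 margin
  n <- cc + d         # row-2 margin
  k <- a + cc         # column-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Sample odds ratio with Woolf confidence interval and Fisher p
#'
#' The estimator is the sample odds ratio (ad)/(bc) with the
#' Haldane-Anscombe +0.5 continuity correction applied iff any cell is zero;
#' the 95% CI is Woolf's interval `exp(log(OR) +/- 1.96 * SE(log OR))` on the
#' (corrected) cells and the p-value is the two-sided Fisher exact test on
#' the uncorrected table.
#'
#' @inheritParams fisher_two_sided
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"or_test"`; see [tidy.or_test()] /
#'   [glance.or_test()].
#' @export
#' @examples
#' odds_ratio_ci(c(8, 2, 1, 5))
odds_ratio_ci <- function(t, conf_level = 0.95) {
  t <- as_2x2(t)
  corrected <- if (any(t == 0)) t + 0.5 else t
  est <- (corrected[1] * corrected[4]) / (corrected[2] * corrected[3])
  se <- sqrt(sum(1 / corrected))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      table = matrix(t, 2L, 2L, byrow = TRUE),
      odds_ratio = est,
      ci_low = exp(log(est) - z * se),
      ci_high = exp(log(est) + z * se),
      p_two_sided = fisher_two_sided(t),
      conf_level = conf_level,
      corrected = any(t == 0)
    ),
    class = "or_test"
  )
}

#' @export
print.or_test <- function(x, ...) {
  cat(sprintf(
    "Sample odds ratio: %.3f  [%d%% CI %.3f-%.3f]%s\n  Fisher two-sided p = %.4g\n",
    x$odds_ratio, round(100 * x$conf_level), x$ci_low, x$ci_high,
    if (x$corrected) "  (Haldane-Anscombe corrected)" else "",
    x$p_two_sided))
  invisible(x)
}

#' Tidy an odds-ratio test
#'
#' @param x An `"or_test"` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @export
tidy.or_test <- function(x, ...) {
  tibble(estimate = x$odds_ratio, conf.low = x$ci_low, conf.high = x$ci_high,
         p.value = x$p_two_sided)
}

#' One-row model summary of an odds-ratio test
#'
#' @inheritParams tidy.or_test
#' @return A one-row tibble adding the table total and correction flag.
#' @export
glance.or_test <- function(x, ...) {
  tibble(estimate = x$odds_ratio, conf.low = x$ci_low, conf.high = x$ci_high,
         p.value = x$p_two_sided, n = sum(x$table),
         corrected = x$corrected, conf.level = x$conf_level)
}

#' Odds ratios of evidence features between disease and non-disease genes
#'
#' For each requested feature, cross-tabulates gene-set membership (`group`
#' column, TRUE row) against the feature flag on the genes where the feature
#' has data, and reports the sample OR, Woolf CI and Fisher p.
#'
#' @param master Master table (or any data frame of logical flags).
#' @param group Tidy-eval column defining the gene set (e.g.
#'   `is_omim_clinical`).
#' @param features Character vector of logical feature columns (default:
#'   mouse lethality, aggregated cell essentiality, whole-gene constraint
#'   flags).
#' @return A tidy tibble with one row per feature.
#' @export
association_odds_ratios <- function(master, group = .data$is_omim_clinical,
                                    features = c("mouse_lethal",
                                                 "essential_agg",
                                                 "missense_constrained",
                                                 "lof_constrained")) {
  purrr::map_dfr(features, function(f) {
    tab <- contingency_2x2(master, {{ group }}, .data[[f]])
    dplyr::bind_cols(tibble(feature = f), tidy(odds_ratio_ci(tab)))
  })
}

#' Constraint proportions stratified by inheritance class
#'
#' Restricted to OMIM-clinical genes (optionally the prenatal/infantile
#' lethal subset) with constraint scores; genes without scores are excluded
#' from every denominator. Proportions are reported for whole-gene missense
#' constraint, regional-only missense constraint (regional metrics positive
#' but missense z below threshold and no LoF/whole-gene call), and LoF
#' constraint.
#'
#' @param master Master table.
#' @param stratum `"all_omim"` or `"prenatal_lethal"` (List B, i.e.
#'   `lethal_class != "none"`).
#' @return A tibble with one row per inheritance class present: `n` (scored
#'   genes), numerators and percentages.
#' @export
constraint_by_inheritance <- function(master,
                                      stratum = c("all_omim",
                                                  "prenatal_lethal")) {
  stratum <- match.arg(stratum)
  base <- filter(master, .data$is_omim_clinical, .data$has_scores)
  if (stratum == "prenatal_lethal") {
    base <- filter(base, .data$lethal_class != "none")
  }
  if (nrow(base) == 0L) {
    return(tibble(inheritance_class = character(0), n = integer(0),
                  n_missense = integer(0), pct_missense = double(0),
                  n_regional_only = integer(0), pct_regional_only = double(0),
                  n_lof = integer(0), pct_lof = double(0)))
  }
  base |>
    mutate(inheritance_class = factor(
      dplyr::coalesce(.data$inheritance_class, "unknown"),
      INHERITANCE_CLASSES)) |>
    group_by(.data$inheritance_class) |>
    summarise(
      n = dplyr::n(),
      n_missense = sum(.data$missense_constrained),
      n_regional_only = sum(.data$constraint_category == "regional_only"),
      n_lof = sum(.data$lof_constrained),
      .groups = "drop"
    ) |>
    mutate(pct_missense = 100 * .data$n_missense / .data$n,
           pct_regional_only = 100 * .data$n_regional_only / .data$n,
           pct_lof = 100 * .data$n_lof / .data$n,
           inheritance_class = as.character(.data$inheritance_class)) |>
    relocate("inheritance_class", "n", "n_missense", "pct_missense",
             "n_regional_only", "pct_regional_only", "n_lof", "pct_lof")
}

#' Hypergeometric GO-slim enrichment with BH-FDR
#'
#' For each annotated term, tests over-representation of the study set
#' against the background universe with the hypergeometric upper tail
#' P(X >= k); BH adjustment is applied within each GO namespace (mirroring
#' separate component/function/process panels) and terms with `q_bh <= alpha`
#' are flagged significant.
#'
#' @param study Character vector of study-set gene symbols (must be a subset
#'   of `background`).
#' @param background Character vector defining the background universe.
#' @param annotations Annotation tibble (`symbol`, `go_id`, `namespace`).
#' @param alpha Significance cutoff on the BH-adjusted q (default 0.025).
#' @return A tibble with one row per term: `go_id`, `namespace`, `k`
#'   (study hits), `n` (study size), `K` (background hits), `N` (background
#'   size), `p_hyper`, `q_bh`, `significant`; sorted by q then p.
#' @export
hypergeom_enrichment <- function(study, background, annotations,
                                 alpha = 0.025) {
  study <- unique(study)
  background <- unique(background)
  if (!all(study %in% background)) {
    abort("study set is not a subset of the background",
          class = "devlethal_validation_error")
  }
  ann <- filter(annotations, .data$symbol %in% background) |>
    distinct(.data$symbol, .data$go_id, .data$namespace)
  N <- length(background)
  n <- length(study)
  res <- ann |>
    group_by(.data$go_id, .data$namespace) |>
    summarise(K = dplyr::n(),
              k = sum(.data$symbol %in% study),
              .groups = "drop") |>
    mutate(n = n, N = N,
           p_hyper = phyper(.data$k - 1L, .data$K, N - .data$K, n,
                            lower.tail = FALSE)) |>
    group_by(.data$namespace) |>
    mutate(q_bh = p.adjust(.data$p_hyper, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$q_bh <= alpha) |>
    arrange(.data$q_bh, .data$p_hyper) |>
    relocate("go_id", "namespace", "k", "n", "K", "N", "p_hyper", "q_bh",
             "significant")
  res
}

#' Comparative enrichment between two disjoint gene sets
#'
#' Each set is tested against the pooled union as reference: for a term with
#' K hits among the pooled genes, the hit count within set A is tested by the
#' hypergeometric upper tail (and symmetrically for B). BH adjustment is
#' applied within each direction and namespace. Per-term annotation
#' proportions in each set are emitted for shading comparative figures.
#'
#' @param set_a,set_b Disjoint character vectors of gene symbols.
#' @param annotations Annotation tibble (`symbol`, `go_id`, `namespace`).
#' @param alpha Significance cutoff (default 0.025).
#' @param adjust `"BH"` (cutoff applied to q, the default) or `"none"`
#'   (cutoff applied to the raw p).
#' @return A tibble with one row per (term, direction): `direction` (
#'   `"A"` or `"B"`), hit counts, `prop_a`, `prop_b`, `p_hyper`, `q_bh`,
#'   `significant`.
#' @export
comparative_enrichment <- function(set_a, set_b, annotations, alpha = 0.025,
                                   adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(intersect(set_a, set_b)) > 0L) {
    abort("the two gene sets must be disjoint",
          class = "devlethal_validation_error")
  }
  pooled <- c(set_a, set_b)
  ann <- filter(annotations, .data$symbol %in% pooled) |>
    distinct(.data$symbol, .data$go_id, .data$namespace)
  counts <- ann |>
    group_by(.data$go_id, .data$namespace) |>
    summarise(K = dplyr::n(),
              k_a = sum(.data$symbol %in% set_a),
              k_b = sum(.data$symbol %in% set_b),
              .groups = "drop")
  one_direction <- function(k, n_set, label) {
    counts |>
      mutate(direction = label, k = k,
             n = n_set, N = length(pooled),
             prop_a = .data$k_a / length(set_a),
             prop_b = .data$k_b / length(set_b),
             p_hyper = phyper(k - 1L, .data$K, length(pooled) - .data$K,
                              n_set, lower.tail = FALSE)) |>
      group_by(.data$namespace) |>
      mutate(q_bh = p.adjust(.data$p_hyper, method = "BH")) |>
      ungroup()
  }
  res <- bind_rows(one_direction(counts$k_a, length(set_a), "A"),
                   one_direction(counts$k_b, length(set_b), "B")) |>
    mutate(significant = (if (adjust == "BH") .data$q_bh else .data$p_hyper)
           <= alpha) |>
    arrange(.data$direction, .data$q_bh, .data$p_hyper) |>
    select("go_id", "namespace", "direction", "k", "n", "K", "N",
           "prop_a", "prop_b", "p_hyper", "q_bh", "significant")
  res
}
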