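mouse_rec <- function(symbol, zygosity = "hom", attr = "null_knockout",
                      n_genes = 1L, terms = character(0), source = "MGI") {
  tibble::tibble(symbol = symbol, source = source, zygosity = zygosity,
                 allele_attribute = attr, n_genes_affected = n_genes,
                 mp_terms = list(terms))
}

test_that("eligibility keeps single-gene null/hypomorph alleles only", {
  recs <- dplyr::bind_rows(
    mouse_rec("A", n_genes = 2L, terms = "MP:0011100"),
    mouse_rec("B", attr = "other", terms = "MP:0011100"),
    mouse_rec("C", attr = "hypomorph", terms = "MP:0011100"),
    mouse_rec("D", zygosity = "het", terms = "MP:0011100"))
  expect_setequal(filter_eligible(recs)$symbol, c("C", "D"))
  expect_equal(filter_eligible(recs, homozygous_only = TRUE)$symbol, "C")
})

test_that("lethality classification separates recessive and other routes", {
  recs <- dplyr::bind_rows(
    mouse_rec("PRE", terms = "MP:0011100"),                    # hom preweaning
    mouse_rec("HET", zygosity = "het", terms = "MP:0002080"),  # het-only lethal
    mouse_rec("HET", terms = "MP:0001392"),                    # benign hom
    mouse_rec("GAIT", terms = c("MP:0001392", "MP:0002066")))  # benign only
  calls <- classify_mouse_lethal(recs)

  pre <- calls[calls$symbol == "PRE", ]
  expect_true(pre$lethal_recessive)
  expect_equal(pre$stage, "preweaning_postnatal")

  het <- calls[calls$symbol == "HET", ]
  expect_false(het$lethal_recessive)
  expect_true(het$outside_recessive_filter)
  expect_equal(het$stage, "prenatal")

  gait <- calls[calls$symbol == "GAIT", ]
  expect_false(gait$lethal_recessive)
  expect_equal(gait$stage, "none")
})

test_that("multi-gene alleles and premature death never set the lethal flag", {
  recs <- dplyr::bind_rows(
    mouse_rec("MULTI", n_genes = 2L, terms = "MP:0011100"),
    mouse_rec("MULTI", terms = "MP:0001392"),
    mouse_rec("PREM", terms = "MP:0002083"))
  calls <- classify_mouse_lethal(recs)
  multi <- calls[calls$symbol == "MULTI", ]
  expect_false(multi$lethal_any_zygosity)
  expect_false(multi$outside_recessive_filter)
  prem <- calls[calls$symbol == "PREM", ]
  expect_false(prem$lethal_recessive)
  expect_true(prem$premature_death)
})

test_that("the earliest stage wins when several lethal terms match", {
  recs <- mouse_rec("E", terms = c("MP:0011100", "MP:0002081", "MP:0008762"))
  calls <- classify_mouse_lethal(recs)
  expect_equal(calls$stage, "embryonic")
})

test_that("unknown MP terms are ignored but tallied", {
  recs <- mouse_rec("U", terms = c("MP:9999999", "MP:0011100"))
  calls <- classify_mouse_lethal(recs)
  expect_true(calls$lethal_recessive)
  expect_equal(attr(calls, "term_report")$unknown_terms, "MP:9999999")
})

test_that("cross-source concordance counts shared hom-data genes", {
  mk_calls <- function(lethal) {
    tibble::tibble(symbol = names(lethal), lethal_recessive = unname(lethal),
                   hom_data = TRUE)
  }
  a <- mk_calls(c(A = TRUE, B = TRUE, C = FALSE))
  b <- mk_calls(c(A = TRUE, B = FALSE, C = FALSE))
  conc <- cross_source_concordance(a, b)
  expect_equal(conc$concordance, 2 / 3)
  expect_equal(conc$n_shared, 3L)

  expect_equal(cross_source_concordance(a, a)$concordance, 1)
  d <- mk_calls(c(X = TRUE))
  expect_error(cross_source_concordance(a, d),
               class = "devlethal_validation_error")
})

test_that("enlarging the lethal term set never unmakes a lethal call", {
  sim <- sim_messy()
  records <- dplyr::bind_rows(sim$bundle$mgi, sim$bundle$impc)
  base_terms <- default_lethal_terms()
  small <- base_terms
  small$lethal_terms <- purrr::map(base_terms$lethal_terms, head, 1L)
  calls_small <- classify_mouse_lethal(records, small)
  calls_full <- classify_mouse_lethal(records, base_terms)
  j <- dplyr::inner_join(calls_small, calls_full, by = "symbol",
                         suffix = c(".small", ".full"))
  expect_true(all(!j$lethal_recessive.small | j$lethal_recessive.full))
})

test_that("lethal, outside-filter and non-lethal genes partition the data", {
  calls <- pipeline_messy()$mouse_calls
  n <- sum(calls$lethal_recessive) +
    sum(calls$outside_recessive_filter) +
    sum(!calls$lethal_recessive & !calls$outside_recessive_filter)
  expect_equal(n, nrow(calls))
  expect_true(all(!calls$lethal_recessive | calls$lethal_any_zygosity))
})

test_that("zero-noise classification recovers planted lethality and stages", {
  sim <- sim_clean()
  res <- pipeline_clean()
  j <- dplyr::left_join(sim$truth, res$master, by = "symbol",
                        suffix = c(".t", ".m"))
  expect_equal(n_mismatch(j$mouse_lethal.t, j$mouse_lethal.m), 0L)
  expect_equal(n_mismatch(j$mouse_stage.t, j$mouse_stage.m), 0L)
  expect_equal(n_mismatch(j$outside_recessive_filter.t,
                          j$outside_recessive_filter.m), 0L)
  expect_equal(n_mismatch(j$premature_death.t, j$premature_death.m), 0L)
})

test_that("per-source calls reproduce the planted cross-source concordance", {
  sim <- sim_messy()
  calls_mgi <- classify_mouse_lethal(sim$bundle$mgi)
  calls_impc <- classify_mouse_lethal(sim$bundle$impc)
  conc <- cross_source_concordance(calls_mgi, calls_impc)
  expect_equal(conc$n_shared, sim$planted$n_shared)
  expect_equal(conc$concordance, sim$planted$concordance)
})
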