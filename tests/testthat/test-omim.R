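test_that("phenotype string syntax is parsed into modifiers and mapping key", {
  p <- parse_phenotype_string("?Cataract 42 (3)")
  expect_true(p$provisional)
  expect_equal(p$mapping_key, 3L)
  expect_false(p$susceptibility)

  p <- parse_phenotype_string("{Diabetes, susceptibility to} (3)")
  expect_true(p$susceptibility)
  expect_false(p$provisional)

  p <- parse_phenotype_string("[Blood group, variant] (3)")
  expect_true(p$nondisease)

  p <- parse_phenotype_string("Myopathy, congenital (3), Autosomal recessive")
  expect_equal(p$inheritance_modes[[1]], "AR")
  expect_false(any(p$nondisease, p$susceptibility, p$provisional, p$somatic))

  p <- parse_phenotype_string("Leukemia, acute myeloid, somatic (3)")
  expect_true(p$somatic)

  p <- parse_phenotype_string("Deletion syndrome (4)")
  expect_true(p$contiguous_deletion)

  p <- parse_phenotype_string("Trait with no key")
  expect_equal(p$mapping_key, 0L)

  p <- parse_phenotype_string(
    "Disorder X (3), Autosomal recessive, Autosomal dominant")
  expect_setequal(p$inheritance_modes[[1]], c("AR", "AD"))

  p <- parse_phenotype_string("Disorder Y (3), X-linked recessive")
  expect_equal(p$inheritance_modes[[1]], "XLR")
})

test_that("clinical relevance filtering applies exclusions per phenotype", {
  universe <- tibble::tibble(symbol = c("G1", "G2", "G3", "G4"))
  genemap <- tibble::tibble(
    symbol = c("G1", "G1", "G2", "G3", "G4"),
    phenotype = c("Carcinoma, somatic (3)",
                  "Myopathy, congenital (3), Autosomal recessive",
                  "{Asthma, susceptibility to} (3)",
                  "Unmapped trait (1)",
                  "?Provisional disorder (3)"),
    clinical_synopsis = NA_character_)
  curated <- filter_clinically_relevant(parse_genemap(genemap), universe)
  # G1 keeps its germline key-3 phenotype despite the somatic one
  expect_equal(curated$symbol, "G1")
  expect_equal(curated$n_qualifying, 1L)
  log <- attr(curated, "exclusion_log")
  expect_setequal(log$reason[log$symbol == "G2"], "susceptibility")
  expect_setequal(log$reason[log$symbol == "G4"], "provisional")
})

test_that("genes outside the protein-coding universe are excluded", {
  genemap <- tibble::tibble(
    symbol = c("IN1", "OUT1"),
    phenotype = rep("Disorder (3), Autosomal dominant", 2),
    clinical_synopsis = NA_character_)
  curated <- filter_clinically_relevant(parse_genemap(genemap), c("IN1"))
  expect_equal(curated$symbol, "IN1")
  log <- attr(curated, "exclusion_log")
  expect_equal(log$reason[log$symbol == "OUT1"],
               "not in protein-coding universe")
})

test_that("inheritance classification follows the precedence order", {
  expect_equal(classify_inheritance("AR"), "AR")
  expect_equal(classify_inheritance("AD"), "AD")
  expect_equal(classify_inheritance(c("AR", "AD")), "AR/AD")
  expect_equal(classify_inheritance(character(0)), "unknown")
  expect_equal(classify_inheritance(c("AR", "XLR")), "XL")
  expect_equal(classify_inheritance(c("XLD", "AD")), "XL")
  expect_equal(classify_inheritance(c("MT", "XLR", "AR")), "MT")
  expect_equal(classify_inheritance("XL_unspecified"), "XL")
  expect_equal(classify_inheritance("other"), "unknown")
})

test_that("lethality tiers match phrases with List A precedence", {
  expect_equal(flag_lethal_phenotypes("fetal demise at 22 weeks gestation"),
               "listA")
  expect_equal(flag_lethal_phenotypes("death in infancy"), "listB")
  expect_equal(flag_lethal_phenotypes("adult-onset ataxia"), "none")
  # List A phrase wins even when a List B phrase also matches
  expect_equal(flag_lethal_phenotypes(
    "neonatal death; described as a lethal disorder"), "listA")
  # matching is case-insensitive over squished whitespace
  expect_equal(flag_lethal_phenotypes("Neonatal   DEATH reported"), "listA")
  # exclusion phrases veto the bare match
  expect_equal(flag_lethal_phenotypes("a sublethal allele"), "none")
})

test_that("lexicons with overlapping tiers are rejected", {
  lex <- default_lethality_lexicon()
  lex$listB_terms <- c(lex$listB_terms, lex$listA_terms[1])
  expect_error(flag_lethal_phenotypes("x", lex),
               class = "devlethal_validation_error")
})

test_that("manual-review overrides can reject a lethality call", {
  sim <- sim_clean()
  parsed <- parse_genemap(sim$bundle$genemap)
  curated <- filter_clinically_relevant(parsed, sim$bundle$universe)
  lethal_gene <- curated$symbol[curated$lethal_class != "none"][1]
  over <- tibble::tibble(symbol = lethal_gene, decision = "reject")
  curated2 <- filter_clinically_relevant(parsed, sim$bundle$universe,
                                         overrides = over)
  expect_equal(curated2$lethal_class[curated2$symbol == lethal_gene], "none")
  expect_equal(curated2$lethal_class[curated2$symbol != lethal_gene],
               curated$lethal_class[curated$symbol != lethal_gene])
})

test_that("curation is idempotent and List A is nested in List B", {
  sim <- sim_clean()
  parsed <- parse_genemap(sim$bundle$genemap)
  curated <- filter_clinically_relevant(parsed, sim$bundle$universe)

  # idempotence: re-curating the surviving rows changes nothing
  kept_rows <- dplyr::semi_join(parsed, curated, by = "symbol")
  again <- filter_clinically_relevant(kept_rows, sim$bundle$universe)
  # the exclusion log legitimately differs (already-excluded phenotypes are
  # gone from the input), so compare the retained gene-level columns only
  strip <- function(df) {
    attr(df, "exclusion_log") <- NULL
    dplyr::select(df, -"n_qualifying")
  }
  expect_equal(strip(again),
               strip(dplyr::semi_join(curated, again, by = "symbol")))

  # at the gene level the explicit tier is a subset of the permissive tier
  lista <- curated$symbol[curated$lethal_class == "listA"]
  listb <- curated$symbol[curated$lethal_class %in% c("listA", "listB")]
  expect_true(all(lista %in% listb))
  expect_gt(length(lista), 0L)
})

test_that("zero-noise curation recovers the planted disease set exactly", {
  sim <- sim_clean()
  res <- pipeline_clean()
  truth <- sim$truth
  expect_setequal(res$curated$symbol, truth$symbol[truth$is_disease])
  j <- dplyr::inner_join(res$curated, truth, by = "symbol",
                         suffix = c(".got", ".want"))
  expect_equal(n_mismatch(j$lethal_class.got, j$lethal_class.want), 0L)
  expect_equal(n_mismatch(j$inheritance_class.got, j$inheritance_class.want),
               0L)
})
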