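test_that("configuration validation rejects out-of-range parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_disease = 1.5),
               class = "devlethal_config_error")
  expect_error(sim_config(mouse_missingness = -0.1),
               class = "devlethal_config_error")
  expect_error(sim_config(inheritance_mix = c(AR = 0.5, AD = 0.4)),
               class = "devlethal_config_error")
  expect_error(sim_config(n_genes = 5),
               class = "devlethal_config_error")
})

test_that("generation is deterministic, in memory and on disk", {
  cfg <- sim_config(n_genes = 150, seed = 99)
  a <- generate_sources(cfg)
  b <- generate_sources(cfg)
  expect_identical(a$bundle, b$bundle)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_sources(cfg, dir = d1)$files
  f2 <- generate_sources(cfg, dir = d2)$files
  for (role in setdiff(names(f1), "sources")) {  # sources.yaml holds paths
    expect_identical(readLines(f1[[role]]), readLines(f2[[role]]),
                     info = role)
  }
})

test_that("per-source substreams are independent of which sources run", {
  cfg <- sim_config(n_genes = 300, seed = 31)
  full <- generate_sources(cfg)
  mouse_only <- generate_sources(cfg, sources = "mouse")
  cells_only <- generate_sources(cfg, sources = "cells")
  expect_identical(mouse_only$bundle$mgi, full$bundle$mgi)
  expect_identical(mouse_only$bundle$impc, full$bundle$impc)
  expect_identical(cells_only$bundle$essentiality, full$bundle$essentiality)
  expect_null(mouse_only$bundle$universe)
  # a partial bundle cannot be written to disk
  expect_error(
    generate_sources(cfg, dir = withr::local_tempdir(), sources = "mouse"),
    class = "devlethal_config_error")
})

test_that("realised marginals stay within binomial bounds of the presets", {
  cfg <- sim_config(n_genes = 4000, seed = 23)
  sim <- cached("marginals", generate_sources(cfg, sources = c(
    "universe", "genemap", "mouse", "cells")))
  want <- expected_counts(cfg)
  bound <- function(n, p) 5 * sqrt(n * p * (1 - p))

  expect_lt(abs(sum(sim$truth$is_disease) - want$n_disease),
            bound(cfg$n_genes, cfg$frac_disease))
  expect_lt(abs(sum(sim$truth$lethal_class %in% c("listA", "listB")) -
                  want$n_lethal),
            bound(want$n_disease, cfg$frac_lethal_given_disease) +
              bound(cfg$n_genes, cfg$frac_disease))
  expect_lt(abs(sum(sim$truth$mouse_data) - want$n_mouse_data),
            bound(cfg$n_genes, 1 - cfg$mouse_missingness))
  # lethal classes only occur on disease genes by construction
  expect_true(all(sim$truth$is_disease[
    sim$truth$lethal_class %in% c("listA", "listB")]))
  expect_true(all(is.na(sim$truth$lethal_class[!sim$truth$is_disease])))
})

test_that("call-level noise degrades essentiality recovery monotonically", {
  mismatches <- vapply(c(0, 0.01, 0.05), function(noise) {
    sim <- generate_sources(
      sim_config(n_genes = 400, seed = 12, essentiality_noise = noise,
                 cell_missingness = 0),
      sources = "cells")
    summ <- aggregate_essentialome(sim$bundle$essentiality)
    j <- dplyr::left_join(sim$truth, summ, by = "symbol",
                          suffix = c(".t", ".m"))
    n_mismatch(j$essential_agg.t, j$essential_agg.m)
  }, integer(1))
  expect_equal(mismatches[1], 0L)
  expect_true(all(diff(mismatches) >= 0L))
})

test_that("written bundles round-trip through the readers without loss", {
  dir <- withr::local_tempdir()
  sim <- generate_sources(sim_config(n_genes = 250, seed = 4), dir = dir)
  expect_no_warning(
    bundle <- read_source_bundle(file.path(dir, "sources.yaml")))
  # the reader keeps only the protein-coding universe
  expect_equal(nrow(bundle$universe),
               sum(sim$bundle$universe$locus_type == "protein-coding"))
  expect_equal(nrow(bundle$genemap), nrow(sim$bundle$genemap))
  expect_equal(nrow(bundle$mouse),
               nrow(sim$bundle$mgi) + nrow(sim$bundle$impc))
  expect_setequal(
    unlist(bundle$mouse$mp_terms[bundle$mouse$source == "MGI"]),
    unlist(sim$bundle$mgi$mp_terms))
  expect_equal(bundle$constraint$pLI, sim$bundle$constraint$pLI)
  expect_setequal(bundle$regional$gamma, sim$bundle$regional$gamma)
  expect_equal(nrow(bundle$go), nrow(sim$bundle$go))
  # the pipeline runs end to end on the re-read bundle
  res <- run_pipeline(bundle)
  expect_equal(nrow(res$master),
               sum(sim$bundle$universe$locus_type == "protein-coding"))
})

test_that("the full-scale preset only rescales the gene count", {
  cfg <- paper_scale_config(seed = 2)
  expect_equal(cfg$n_genes, 19196L)
  base <- sim_config(seed = 2)
  expect_equal(cfg$frac_disease, base$frac_disease)
  want <- expected_counts(cfg)
  expect_equal(round(want$n_disease), 3187)
  expect_equal(round(want$n_lethal), 624)
  expect_equal(round(want$n_listA), 344)
  expect_equal(round(want$n_mouse_data), 9397)
})
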