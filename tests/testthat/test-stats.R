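test_that("two-sided Fisher p matches the enumeration oracle", {
  expect_equal(fisher_two_sided(c(5, 5, 5, 5)), 1.0)
  expect_equal(fisher_two_sided(c(0, 10, 0, 7)), 1.0)
  expect_equal(fisher_two_sided(c(8, 2, 1, 5)), 0.034965034965035,
               tolerance = 1e-12)
  expect_error(fisher_two_sided(c(0, 0, 0, 0)),
               class = "devlethal_parameter_error")

  # randomised property check against the choose()-based oracle
  set.seed(11)
  for (i in 1:200) {
    t <- as.double(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
    expect_equal(fisher_two_sided(t),
                 oracle_fisher(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with the reference exact test", {
  set.seed(12)
  for (i in 1:50) {
    t <- as.double(rmultinom(1, sample(8:200, 1), c(0.3, 0.2, 0.3, 0.2)))
    m <- matrix(t, 2, 2, byrow = TRUE)
    expect_equal(fisher_two_sided(t), stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("odds ratios follow the sample formula with Woolf intervals", {
  or <- odds_ratio_ci(c(8, 2, 1, 5))
  expect_equal(or$odds_ratio, 20)
  expect_equal(or$ci_low, exp(log(20) - qnorm(0.975) *
                                sqrt(1 / 8 + 1 / 2 + 1 / 1 + 1 / 5)))
  expect_true(or$ci_low <= or$odds_ratio & or$odds_ratio <= or$ci_high)

  flat <- odds_ratio_ci(c(10, 10, 10, 10))
  expect_equal(flat$odds_ratio, 1)
  expect_true(flat$ci_low < 1 & flat$ci_high > 1)

  # zero cells trigger the Haldane-Anscombe correction
  z <- odds_ratio_ci(c(5, 0, 3, 4))
  expect_true(z$corrected)
  expect_equal(z$odds_ratio, (5.5 * 4.5) / (0.5 * 3.5))

  td <- tidy(or)
  expect_equal(td$estimate, 20)
  expect_named(td, c("estimate", "conf.low", "conf.high", "p.value"))
  expect_equal(glance(or)$n, 16)
})

test_that("swapping the table rows inverts the OR and preserves p", {
  set.seed(13)
  for (i in 1:25) {
    t <- as.double(rmultinom(1, 60, c(0.3, 0.2, 0.3, 0.2))) + 1
    a <- odds_ratio_ci(t)
    b <- odds_ratio_ci(t[c(3, 4, 1, 2)])
    expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-12)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches tail and BH oracles", {
  background <- sprintf("g%03d", 1:100)
  study <- background[1:10]
  # one term with 10 background genes, 5 of them in the study set
  ann <- tibble::tibble(
    symbol = c(background[c(1:5, 60:64)], background[11:40]),
    go_id = c(rep("GO:0000001", 10), rep("GO:0000002", 30)),
    namespace = "process")
  res <- hypergeom_enrichment(study, background, ann)
  p1 <- res$p_hyper[res$go_id == "GO:0000001"]
  expect_equal(p1, oracle_hyper_tail(5, 10, 100, 10), tolerance = 1e-12)
  expect_equal(p1, 0.00067162774826505, tolerance = 1e-10)
  # a term with zero study hits has p = 1
  expect_equal(res$p_hyper[res$go_id == "GO:0000002"], 1)
  expect_error(hypergeom_enrichment(c(study, "absent"), background, ann),
               class = "devlethal_validation_error")
})

test_that("BH adjustment matches the step-up formula and is idempotent", {
  p <- c(0.001, 0.01, 0.02, 0.04)
  q <- stats::p.adjust(p, method = "BH")
  expect_equal(q, c(0.004, 0.02, 4 / 150, 0.04), tolerance = 1e-12)
  expect_equal(q, oracle_bh(p))
  # order-preserving
  set.seed(14)
  pr <- runif(50)
  expect_equal(order(oracle_bh(pr), pr), order(stats::p.adjust(pr, "BH"), pr))
})

test_that("comparative enrichment handles extreme and null terms", {
  set_a <- sprintf("a%02d", 1:20)
  set_b <- sprintf("b%02d", 1:20)
  ann <- dplyr::bind_rows(
    tibble::tibble(symbol = set_a[1:10], go_id = "GO:0000010",
                   namespace = "process"),          # A-exclusive term
    tibble::tibble(symbol = c(set_a[1:5], set_b[1:5]), go_id = "GO:0000011",
                   namespace = "process"))          # balanced term
  res <- comparative_enrichment(set_a, set_b, ann)
  excl <- res[res$go_id == "GO:0000010", ]
  expect_true(excl$significant[excl$direction == "A"])
  expect_equal(excl$prop_b[1], 0)
  bal <- res[res$go_id == "GO:0000011", ]
  expect_false(any(bal$significant))
  expect_error(comparative_enrichment(set_a, c(set_b, set_a[1]), ann),
               class = "devlethal_validation_error")
})

test_that("comparative enrichment recovers planted skewed terms", {
  sim <- sim_messy()
  truth <- sim$truth
  dominant <- truth$symbol[truth$is_disease &
                             truth$inheritance_class %in% c("AD", "XL")]
  recessive <- truth$symbol[truth$is_disease &
                              truth$inheritance_class == "AR"]
  res <- comparative_enrichment(dominant, recessive, sim$bundle$go)
  hits_a <- res$go_id[res$direction == "A" & res$significant]
  hits_b <- res$go_id[res$direction == "B" & res$significant]
  expect_setequal(hits_a, sim$planted$dominant_terms)
  expect_setequal(hits_b, sim$planted$recessive_terms)
})

test_that("stratified constraint proportions recover planted per-class rates", {
  sim <- sim_clean()
  res <- pipeline_clean()
  tab <- constraint_by_inheritance(res$master, "all_omim")
  truth <- sim$truth[sim$truth$is_disease & sim$truth$has_scores, ]
  want <- truth |>
    dplyr::count(inheritance_class,
                 wt = as.integer(missense_constrained), name = "n_mis")
  j <- dplyr::inner_join(tab, want, by = "inheritance_class")
  expect_equal(j$n_missense, j$n_mis)
  expect_true(all(tab$pct_missense >= 0 & tab$pct_missense <= 100))
  expect_true(all(tab$n_missense <= tab$n & tab$n_lof <= tab$n))

  pren <- constraint_by_inheritance(res$master, "prenatal_lethal")
  expect_true(sum(pren$n) <=
                sum(res$master$lethal_class %in% c("listA", "listB")))

  empty <- constraint_by_inheritance(res$master[0, ], "all_omim")
  expect_equal(nrow(empty), 0L)
})

test_that("feature odds ratios come out tidy with finite intervals", {
  res <- pipeline_messy()
  ors <- association_odds_ratios(res$master)
  expect_named(ors, c("feature", "estimate", "conf.low", "conf.high",
                      "p.value"))
  expect_equal(nrow(ors), 4L)
  expect_true(all(is.finite(ors$estimate) & ors$estimate > 0))
  # disease genes are enriched for mouse lethality in the planted model
  expect_gt(ors$estimate[ors$feature == "mouse_lethal"], 1)
})
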