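---
title: "Methods: curating candidate developmental-lethal genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating candidate developmental-lethal genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devlethal)
```

## The scientific problem

A substantial fraction of protein-coding genes are essential for mammalian
development: knocking them out in the mouse kills the embryo, the neonate or
the pre-weaning pup, and a subset are so fundamental that their loss abolishes
the viability of cultured human cells. Yet only a small minority of human
genes are currently linked to prenatal, perinatal or infantile-lethal
disorders in OMIM. The gap is informative: genes essential for murine
development or cellular viability but *not* yet associated with any human
phenotype are strong candidates for unexplained infertility, recurrent
miscarriage, foetal death and early infantile mortality — conceptuses carrying
biallelic loss of such genes may simply never survive to be ascertained.

`devlethal` implements the informatics pipeline behind this argument. It
curates clinically relevant disease genes and a prenatal/infantile-lethality
tier from OMIM-style genemap records, classifies murine knockout lethality
from MGI/IMPC-style phenotype reports, aggregates cell-line essentiality
screens into an essentialome, categorises genes by genetic constraint,
integrates everything into a one-row-per-gene master table, derives the
candidate developmental-lethal set, and supplies the association statistics
used to characterise these sets. A synthetic-source generator with planted
ground truth makes the whole pipeline testable end to end.

## Curation of clinically relevant genes

`parse_genemap()` and `filter_clinically_relevant()` apply rules that mirror
standard OMIM curation practice:

* Keep phenotype–gene relationships with **mapping key 3** (molecular basis
  known). Mapping key 4 marks contiguous-deletion syndromes, which implicate
  a region rather than the gene, and is excluded.
* Exclude non-disease phenotypes (`[...]` brackets), susceptibility-only
  associations (`{...}` braces), provisional links (`?` prefix) and
  somatic-only phenotypes (whole-word "somatic" match in the label). A gene
  survives when at least one of its phenotypes qualifies; the exclusions are
  applied per phenotype, not per gene, so a gene with both a somatic cancer
  phenotype and a germline disorder is kept.
* Restrict to the protein-coding universe.

Every excluded phenotype row is logged with its reason in the
`"exclusion_log"` attribute, and a manual-review `overrides` table can force
individual genes out of the lethal tier after inspection.

Lethality is tiered with a configurable lexicon
(`default_lethality_lexicon()`, loadable from YAML via
`read_lethality_lexicon()`):

* **List A** — explicit death before birth or within roughly the first three
  months (e.g. "fetal demise", "neonatal death", "stillbirth").
* **List B** — superset of List A adding imprecise infancy wording (e.g.
  "death in infancy", "shortly after birth", bare "lethal").

Phrases are matched as fixed substrings on case-folded, whitespace-squashed
text, with an exclusion list ("sublethal", "lethality in mice", ...) masked
out first. List A wins over List B per gene; `validate_lexicon()` rejects
overlapping tiers.

Inheritance is classified per gene with the precedence
**MT > XL > AR/AD > AD > AR > unknown**: mitochondrial and X-linked patterns
are rare and biologically distinctive, so they take priority over the
autosomal labels they frequently co-occur with; genes with both AR and AD
phenotypes form their own mixed class rather than being forced into either.

## Murine lethality

`classify_mouse_lethal()` consumes per-genotype records from both MGI- and
IMPC-style reports (merged as a union; `cross_source_concordance()` measures
agreement over genes with homozygous data in both):

* The **recessive-null filter** keeps records with a single affected gene,
  a null/knockout or hypomorph allele, assessed as homozygote. This is the
  route that defines `mouse_lethal` (lethal with recessive knockout).
* Lethality is called from a configurable, stage-partitioned MP term set
  (`default_lethal_terms()`): embryonic < prenatal < perinatal <
  pre-weaning/postnatal; the earliest matching stage wins. "Premature death"
  terms are tracked separately and never set the lethal flag.
* Genes lethal only through heterozygous or otherwise filter-ineligible
  single-gene records are flagged `outside_recessive_filter` rather than
  lethal.
* Records whose allele affects more than one gene are ignored on every route:
  a phenotype of a multi-gene deletion cannot be attributed to any single
  member. This is deliberately stricter than only excluding them from the
  recessive filter.

Malformed MP identifiers are dropped with a warning at parse time, and
unknown (non-lexicon) identifiers are tallied in a `"term_report"` attribute
rather than silently discarded. Optional ontology-graph expansion of the term
list (walking MP descendants from an OBO file) is out of scope; the term set
is user-supplied, which covers the same need explicitly.

## The cell essentialome

`aggregate_essentialome()` collapses long-format per-(gene, line, study)
essentiality calls. Eleven distinct cell lines across three studies are
modelled; one line (KBM7-like) is screened by two studies and must count
once, with an essential-if-any collapse over the studies that tested it. A
gene enters the essentialome when essential in **at least three distinct
lines** (`min_lines = 3`), and `essential_all_lines` marks essentiality in
every line. Untested (line, gene) pairs contribute to neither numerator nor
denominator.

Because the three studies screened different gene sets, comparative counts
are defined on the universe tested by **all three** studies
(`restrict_to_tested()`); in the master table the essentiality columns are
masked to `NA` outside that universe, so a gene essential in three lines but
screened by only two studies is treated as having no data, not as essential.

## Genetic constraint

`classify_whole_gene()` applies the conventional inclusive thresholds
mis_z ≥ 3.09 (whole-gene missense constraint) and pLI ≥ 0.9 (LoF
constraint). Regional (sub-gene) constraint is the union of three list-based
metrics (γ-segment, coding-constrained-region and NMD-escape gene lists;
`aggregate_regional()`). `constraint_categories()` assigns each gene exactly
one category: `whole_gene`, `regional_only` (regional evidence without any
whole-gene call), `none`, or `no_data` for genes without scores — which are
excluded from every denominator downstream rather than counted as
unconstrained.

## Integration and the candidate set

`build_master()` joins every evidence stream onto the protein-coding
universe, one row per gene. The cardinal encoding rule is that **absence of
data is never evidence of absence**: genes without mouse data carry
`mouse_lethal = NA`, genes outside the all-three-studies cell universe carry
`essential_agg = NA`, and unscored genes are `no_data`, not unconstrained.

The candidate developmental-lethal set is

> (`mouse_lethal` **or** `essential_agg`) **and not** OMIM-clinical,

where the `NA` flags are treated as `FALSE` only inside this disjunction, so
a gene with no evidence at all can never become a candidate.
`write_master_table()` emits the master table as four TSV sheets (all genes,
candidates, cell-essential-not-mouse-lethal, lethal outside the recessive
filter) plus a JSON manifest, and `read_master_table()` round-trips them.

## Statistics

All tests operate on 2×2 tables built by `contingency_2x2()` (rows where
either flag is `NA` are dropped):

* `fisher_two_sided()` — exact two-sided p by summation of hypergeometric
  point probabilities over all tables with the observed margins that are at
  most as probable as the observed table. Ties are resolved with a relative
  tolerance of `1e-7` on the point probability (the same convention as the
  reference implementation, which the test suite cross-checks but which is
  never called internally).
* `odds_ratio_ci()` — the sample odds ratio (ad)/(bc) with the
  Haldane–Anscombe +0.5 correction applied iff any cell is zero, and Woolf's
  log-OR interval exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)). `tidy()` and
  `glance()` methods are provided.
* `constraint_by_inheritance()` — per-inheritance-class proportions of
  missense, regional-only and LoF constraint among scored OMIM genes,
  optionally restricted to the prenatal/infantile-lethal stratum.
* `hypergeom_enrichment()` — per-term upper-tail hypergeometric test
  P(X ≥ k) against a background universe, BH-adjusted **within each GO
  namespace** (mirroring separate component/function/process panels), cutoff
  q ≤ 0.025.
* `comparative_enrichment()` — two disjoint sets (e.g. dominant vs recessive
  lethal genes), each tested against the pooled union, with per-set
  annotation proportions for figure shading.

## The synthetic-source generator

`generate_sources()` emulates the seven input dialects with a planted,
fully recoverable ground truth. Design choices that matter:

* **Single root seed, fixed substreams.** A gene-level skeleton is drawn on
  substream 1, then each source (universe, genemap, mouse, cells, constraint,
  GO) consumes its own substream. Generating a subset of sources therefore
  never reshuffles the ones that are kept, which makes cheap replicate
  studies of a single statistic possible (`sources = "mouse"`).
* **Exact threshold recovery.** Constraint scores are drawn from truncated
  normals via the inverse CDF, so a gene planted as constrained always lies
  (weakly) above the 3.09/0.9 thresholds and a gene planted unconstrained
  always lies below, even after rounding to six decimals.
* **Lethality as a logistic model.** Latent mouse lethality follows
  logit p = β₀ + β₁·disease + β₂·lethal-tier + β₃·constrained, with
  defaults calibrated so the realised marginals reproduce the documented
  full-scale structure (`paper_scale_config()`): ≈3187 disease genes of
  19,196; 624 prenatal/infantile-lethal (344 List A); ≈39.2% pre-weaning
  lethality among the ≈9397 genes with recessive knockout data; an
  essentialome of ≈14% of the ≈15,903 genes tested by all three studies; and
  ≈84% cross-source lethality concurrence over ≈1290 shared genes.
* **Adversarial decoys.** The universe carries non-coding decoy rows; the
  genemap plants susceptibility, non-disease, provisional and somatic-only
  phenotypes plus extra somatic rows on true disease genes; the mouse tables
  plant benign-phenotype records, heterozygous-only lethals and multi-gene
  deletion alleles carrying lethal terms. At zero noise, every decoy must be
  handled for recovery to be exact — and the test suite requires exact
  recovery.
* **Tunable degradation.** Missingness (mouse, per-study cell, constraint),
  cross-source discordance and per-call essentiality noise are all
  parameters; at their defaults they match the documented data availability,
  and tests verify recovery degrades monotonically as noise grows.

The per-gene truth table exposes every downstream flag (disease status,
lethality tier, inheritance class, mouse lethality and stage, essentialome
membership, constraint category, candidate status), so any stage of the
pipeline can be validated in isolation or end to end. Problem sizes in the
test suite (800–5,000 genes for fixtures, 19,196 or 20,000 for full-scale
and calibration runs) are the package's own choices, balancing statistical
resolution against runtime.

## Numerical and testing choices

* The Fisher tie tolerance (`1e-7`, relative) prevents floating-point
  noise from excluding tables that are exactly tied with the observed one.
* The exact test is validated against an independent `choose()`-based
  enumeration on *every* 2×2 table with grand total ≤ 60 (agreement to
  1e-10), and spot-checked against the reference implementation.
* Woolf-interval calibration is measured directly: across 100 seeded
  20,000-gene replicates with a planted odds ratio of 2.3, the 95% CI must
  cover the planted value at least 93 times; a 1,000-replicate two-group
  binomial null keeps the exact test's rejection rate inside 0.05 ± 3 SE.
* BH adjustment and the hypergeometric tail are delegated to `p.adjust()`
  and `phyper()` and pinned to hand-computed oracle values.

`scripts/acceptance.R --seed <int> --out <path>` runs the full-scale
pipeline and all calibration checks against the *installed* package and
writes the headline quantities as JSON.
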