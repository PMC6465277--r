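# Shared synthetic fixtures, generated once per test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# noise-free mid-sized bundle: every planted flag must be recoverable exactly
sim_clean <- function() {
  cached("clean", generate_sources(sim_config(
    n_genes = 800, seed = 42,
    mouse_missingness = 0, mouse_source_discordance = 0,
    cell_missingness = 0, essentiality_noise = 0,
    constraint_missingness = 0)))
}

# defaults: realistic missingness and cross-source discordance
sim_messy <- function() {
  cached("messy", generate_sources(sim_config(n_genes = 1200, seed = 7)))
}

pipeline_clean <- function() {
  cached("pipeline_clean", run_pipeline(sim_clean()$bundle))
}

pipeline_messy <- function() {
  cached("pipeline_messy", run_pipeline(sim_messy()$bundle))
}

# NA-aware per-column equality for truth-vs-pipeline comparisons
n_mismatch <- function(a, b) {
  sum(!((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)))
}

# independent enumeration oracle for the two-sided Fisher test (choose(),
# not dhyper, so it shares no code path with the implementation)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  supp <- max(0, k - n):min(k, m)
  pr <- vapply(supp,
               function(x) choose(m, x) * choose(n, k - x) / choose(N, k),
               numeric(1))
  pobs <- pr[supp == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# brute-force hypergeometric upper tail P(X >= k)
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  sum(vapply(k:min(K, n),
             function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n),
             numeric(1)))
}

# BH step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
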