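# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the implementation it checks.

# Running-sum KS oracle: walk every threshold of the ranked list, tracking
# the hit fraction against the uniform position, and take the largest
# deviation in each direction.
es_running_sum_oracle <- function(set_s, ranking) {
  n <- length(ranking)
  hits <- ranking %in% set_s
  s <- sum(hits)
  stopifnot(s > 0, s < n)
  cum <- cumsum(hits)
  prev <- c(0, cum[-n])
  a <- max(0, cum / s - seq_len(n) / n)
  b <- max(0, seq_len(n) / n - prev / s)
  if (a >= b) a else -b
}

# Both one-sided deviations of the running sum, via the same walk.
es_deviations_oracle <- function(set_s, ranking) {
  n <- length(ranking)
  hits <- ranking %in% set_s
  s <- sum(hits)
  cum <- cumsum(hits)
  prev <- c(0, cum[-n])
  c(a = max(0, cum / s - seq_len(n) / n),
    b = max(0, seq_len(n) / n - prev / s))
}

# Direct step-up BH oracle: adjusted p of the i-th order statistic is the
# running minimum over j >= i of n * p_(j) / j, clipped at 1.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(n), function(i) min(1, min(n * ps[i:n] / (i:n))), 0)
  adj[order(o)]
}

# Brute-force hypergeometric upper tail by direct pmf summation.
hyper_sum_oracle <- function(k, set_size, universe_size, query_size) {
  ks <- k:min(set_size, query_size)
  sum(stats::dhyper(ks, set_size, universe_size - set_size, query_size))
}

# Exhaustive pairwise-comparison AUROC (positives should score LOWER).
auroc_lower <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, FUN = function(a, b) {
    (a < b) + 0.5 * (a == b)
  })
  mean(cmp)
}

# Brute-force grid search for the variance-prior moment fit.
prior_grid_oracle <- function(s2, df, d0_grid = seq(0.5, 30, by = 0.01)) {
  z <- log(s2)
  target <- var(z) - trigamma(df / 2)
  d0 <- d0_grid[which.min(abs(trigamma(d0_grid / 2) - target))]
  s0 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
              digamma(d0 / 2) - log(d0 / 2))
  c(d0 = d0, s0_sq = s0)
}

# Small simulation bundle used by several fast tests.
tiny_config <- function(...) {
  defaults <- list(n_genes = 500, n_tumor = 10, n_normal = 10, frac_de = 0.1,
                   n_drugs = 20, n_reversers = 5, profile_genes = 200,
                   n_screen_lines = 10, n_tumorlike_lines = 3,
                   n_biomarker_drugs = 2, n_segments = 20, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Build a disease_signature directly from planted membership (bypasses the
# DE stage; used where only downstream logic is under test).
signature_from_lfc <- function(lfc, dataset_id, alpha = 1e-6) {
  de <- tibble::tibble(
    gene = names(lfc), log2FC = unname(lfc),
    t_mod = 0, p = alpha / 10, padj = alpha / 10, mean_expr = 0
  )
  build_signature(de, dataset_id, lfc_cut = 1, alpha = alpha)
}
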