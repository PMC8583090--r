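make_expr <- function(vals, groups, scale = "log_intensity") {
  expression_matrix(vals, scale = scale, groups = groups)
}

one_group_matrix <- function(vals, group) {
  structure(list(values = vals, scale = "log_intensity",
                 groups = setNames(rep(group, ncol(vals)), colnames(vals))),
            class = "expr_matrix")
}

test_that("matched-normal selection ranks exact tumor copies first", {
  set.seed(1)
  ng <- 600
  genes <- sprintf("g%04d", 1:ng)
  # tumors share a gene-level baseline, so they are mutually correlated
  baseline <- rnorm(ng, mean = 6)
  tum_vals <- baseline + matrix(rnorm(ng * 5, sd = 0.3), ng, 5)
  dimnames(tum_vals) <- list(genes, paste0("T", 1:5))
  copies <- tum_vals + matrix(rnorm(ng * 5, sd = 0.01), ng, 5)
  colnames(copies) <- paste0("C", 1:5)
  noise <- matrix(rnorm(ng * 10, mean = 6), ng, 10,
                  dimnames = list(genes, paste0("R", 1:10)))
  pool_vals <- cbind(copies, noise)
  tumors <- one_group_matrix(tum_vals, "tumor")
  pool <- one_group_matrix(pool_vals, "normal")
  expect_setequal(select_matched_normals(tumors, pool, k = 5),
                  paste0("C", 1:5))
  # k = pool size returns the whole pool, ranked
  all_ranked <- select_matched_normals(tumors, pool, k = 15)
  expect_setequal(all_ranked, colnames(pool_vals))
  expect_setequal(head(all_ranked, 5), paste0("C", 1:5))
})

test_that("matched-normal selection recovers the tumor-like cluster", {
  set.seed(2)
  ng <- 800
  centroid_a <- rnorm(ng, 6); centroid_b <- rnorm(ng, 6)
  genes <- sprintf("g%04d", 1:ng)
  draw <- function(centroid, n, prefix) {
    m <- centroid + matrix(rnorm(ng * n, sd = 0.7), ng, n)
    dimnames(m) <- list(genes, paste0(prefix, seq_len(n)))
    m
  }
  tum <- draw(centroid_a, 10, "T")
  pool_vals <- cbind(draw(centroid_a, 60, "A"), draw(centroid_b, 60, "B"))
  tumors <- one_group_matrix(tum, "tumor")
  pool <- one_group_matrix(pool_vals, "normal")
  sel <- select_matched_normals(tumors, pool, k = 50)
  expect_gte(mean(startsWith(sel, "A")), 0.9)
  # agrees with a direct gene-space correlation ranking oracle
  direct <- apply(pool_vals, 2, function(p) {
    median(apply(tum, 2, function(tv) cor(p, tv, method = "spearman")))
  })
  oracle <- names(sort(direct, decreasing = TRUE))[1:50]
  expect_gt(length(intersect(sel, oracle)) / 50, 0.8)
})

test_that("variance-prior fit handles degenerate and scaled inputs", {
  pr <- fit_variance_prior(rep(0.3, 100), df_resid = 10)
  expect_identical(pr$d0, Inf)
  # with d0 = Inf the estimate is the bias-corrected geometric mean, which
  # for constant variances is the common value up to the log-chi-square bias
  expect_equal(pr$s0_sq, 0.3 / exp(digamma(5) - log(5)), tolerance = 1e-10)

  set.seed(4)
  s2 <- 0.05 * 4 / rchisq(5000, 4) * rchisq(5000, 20) / 20
  pr1 <- fit_variance_prior(s2, 20)
  pr2 <- fit_variance_prior(2 * s2, 20)
  expect_equal(pr2$d0, pr1$d0, tolerance = 1e-10)
  expect_equal(pr2$s0_sq, 2 * pr1$s0_sq, tolerance = 1e-10)
  expect_error(fit_variance_prior(c(s2, -1), 20), "positive")
})

test_that("variance-prior fit recovers simulated hyperparameters", {
  set.seed(5)
  df <- 58
  s2 <- 0.05 * 4 / rchisq(20000, 4) * rchisq(20000, df) / df
  pr <- fit_variance_prior(s2, df)
  expect_lt(abs(pr$d0 - 4) / 4, 0.1)
  expect_lt(abs(pr$s0_sq - 0.05) / 0.05, 0.1)
  # trigamma inversion agrees with a brute-force grid oracle
  grid <- prior_grid_oracle(s2, df)
  expect_equal(pr$d0, unname(grid["d0"]), tolerance = 0.02)
  expect_equal(pr$s0_sq, unname(grid["s0_sq"]), tolerance = 1e-3)
})

test_that("variance-prior fit matches the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(6)
  s2 <- 0.08 * 6 / rchisq(10000, 6) * rchisq(10000, 18) / 18
  pr <- fit_variance_prior(s2, 18)
  lf <- limma::fitFDist(s2, df1 = 18)
  expect_equal(pr$d0, lf$df2, tolerance = 0.05 * lf$df2)
  expect_equal(pr$s0_sq, lf$scale, tolerance = 0.05 * lf$scale)
})

test_that("moderated t reduces to the pooled t at d0 = 0 and to z at d0 = Inf", {
  set.seed(7)
  vals <- matrix(rnorm(100 * 12, 5), 100, 12,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:12)))
  m <- make_expr(vals, groups = rep(c("tumor", "normal"), each = 6))
  de0 <- moderated_ttest(m, prior = list(d0 = 0, s0_sq = 1))
  ordinary_p <- apply(vals, 1, function(x) {
    t.test(x[1:6], x[7:12], var.equal = TRUE)$p.value
  })
  expect_equal(de0$p, unname(ordinary_p), tolerance = 1e-12)

  s0 <- 0.7
  dei <- moderated_ttest(m, prior = list(d0 = Inf, s0_sq = s0))
  lfc <- rowMeans(vals[, 1:6]) - rowMeans(vals[, 7:12])
  z <- lfc / sqrt(s0 * (1 / 6 + 1 / 6))
  expect_equal(dei$t_mod, unname(z), tolerance = 1e-12)
  expect_equal(dei$p, unname(2 * pnorm(-abs(z))), tolerance = 1e-12)
})

test_that("moderated t agrees with limma eBayes on the same data", {
  skip_if_not_installed("limma")
  cfg <- tiny_config(n_genes = 1000, n_tumor = 15, n_normal = 15)
  co <- generate_expression_cohort(cfg)
  de <- moderated_ttest(co$matrix)
  design <- cbind(1, co$matrix$groups == "tumor")
  fit <- limma::eBayes(limma::lmFit(co$matrix$values, design))
  expect_equal(de$log2FC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_gt(cor(-log10(de$p), -log10(fit$p.value[, 2])), 0.999)
})

test_that("genes with zero variance everywhere are flagged at p = 1", {
  vals <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4)))
  vals[1, ] <- 3  # constant gene
  m <- make_expr(vals, groups = c("tumor", "tumor", "normal", "normal"))
  de <- moderated_ttest(m, prior = list(d0 = Inf, s0_sq = 0))
  expect_identical(de$flag[1], "zero_variance")
  expect_identical(de$p[1], 1)
})

test_that("BH adjustment matches the closed form and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  set.seed(8)
  p <- runif(1000)
  adj <- bh_adjust(p)
  expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-14)
  expect_true(all(adj >= p))
  # identical rejection sets at any alpha
  for (alpha in c(0.01, 0.05, 0.2)) {
    expect_identical(which(adj < alpha), which(bh_stepup_oracle(p) < alpha))
  }
})

test_that("signature cutoffs follow the |log2FC| > 1, padj < 0.001 rule", {
  de <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    log2FC = c(1.2, 0.9, -1.5, -1.2),
    p = c(1e-5, 1e-10, 1e-6, 0.5),
    padj = c(5e-4, 1e-9, 1e-5, 0.6)
  )
  sig <- build_signature(de, "fix")
  expect_identical(sig$up, "a")       # 1.2 / 5e-4 passes
  expect_identical(sig$down, "c")     # b fails the fold cutoff, d the padj
})

test_that("duplicate probes collapse to the lowest p-value row", {
  de <- tibble::tibble(
    gene = c("a", "a", "b"),
    log2FC = c(2, -2, 3),
    p = c(1e-6, 1e-3, 1e-8),
    padj = c(1e-5, 1e-2, 1e-7)
  )
  sig <- build_signature(de, "dup")
  row <- sig$table[sig$table$gene == "a", ]
  expect_identical(row$p, 1e-6)
  expect_identical(sig$up, c("a", "b"))
})

test_that("swapping group labels swaps the up and down sets exactly", {
  cfg <- tiny_config(n_genes = 1000)
  co <- generate_expression_cohort(cfg)
  m <- co$matrix
  m_flip <- m
  m_flip$groups <- setNames(
    ifelse(m$groups == "tumor", "normal", "tumor"), names(m$groups))
  sig <- build_signature(moderated_ttest(m), "fwd")
  sig_f <- build_signature(moderated_ttest(m_flip), "rev")
  expect_identical(sig$up, sig_f$down)
  expect_identical(sig$down, sig_f$up)
})

test_that("signature building is idempotent and order-independent", {
  cfg <- tiny_config(n_genes = 800)
  co <- generate_expression_cohort(cfg)
  de <- moderated_ttest(co$matrix)
  sig1 <- build_signature(de, "x")
  sig2 <- build_signature(de[sample.int(nrow(de)), ], "x")
  expect_identical(sig1$up, sig2$up)
  expect_identical(sig1$down, sig2$down)
  sig3 <- build_signature(sig1$table, "x")
  expect_identical(sig3$up, sig1$up)
})

test_that("signature intersection counts planted cores and ranks by L1 norm", {
  genes <- sprintf("core%03d", 1:372)
  mk <- function(id, extra_n, lfc_core) {
    extra <- setNames(rep(2, extra_n), sprintf("%s_extra%03d", id, 1:extra_n))
    signature_from_lfc(c(setNames(lfc_core, genes), extra), id)
  }
  sigs <- lapply(1:6, function(i) mk(paste0("d", i), 10 + i, rep(1.5 + i / 10, 372)))
  ov <- intersect_signatures(sigs)
  expect_length(ov$shared_all, 372)
  expect_setequal(ov$shared_all, genes)
  # identical signatures: shared set is the union of either
  ov2 <- intersect_signatures(list(sigs[[1]],
                                   signature_from_lfc(
                                     setNames(rep(2, 372), genes), "dup")))
  expect_length(ov2$shared_all, 372)
  # disjoint signatures share nothing
  s_a <- signature_from_lfc(setNames(rep(2, 20), sprintf("a%02d", 1:20)), "A")
  s_b <- signature_from_lfc(setNames(rep(2, 20), sprintf("b%02d", 1:20)), "B")
  ov3 <- intersect_signatures(list(s_a, s_b))
  expect_length(ov3$shared_all, 0)
  expect_identical(ov3$pairwise$n_shared, 0L)
  expect_error(intersect_signatures(list(s_a, s_a)), "duplicate")
  # L1 ranking: gene with the largest |log2FC| sum comes first
  s1 <- signature_from_lfc(c(g1 = 3, g2 = 1.5), "r1")
  s2 <- signature_from_lfc(c(g1 = 2.5, g2 = -4.5), "r2")
  ov4 <- intersect_signatures(list(s1, s2))
  expect_identical(ov4$top_deg$gene, c("g2", "g1"))
  expect_equal(ov4$top_deg$l1_lfc, c(6, 5.5), tolerance = 1e-12)
})
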