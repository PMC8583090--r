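test_that("cell-line similarity recognises constructed matches and inversions", {
  genes <- sprintf("g%03d", 1:40)
  lfc <- setNames(c(seq(1.2, 3, length.out = 20), seq(-3, -1.2, length.out = 20)),
                  genes)
  sig <- signature_from_lfc(lfc, "s")
  # three lines: proportional to the signature, inverted, unrelated
  set.seed(30)
  base <- 5
  expr <- dplyr::bind_rows(
    tibble::tibble(gene = genes, cell_line = "match",
                   expression = base + 0.5 * lfc),
    tibble::tibble(gene = genes, cell_line = "inverse",
                   expression = base - 0.5 * lfc),
    tibble::tibble(gene = genes, cell_line = "noise",
                   expression = base + rnorm(40, sd = 0.1)),
    tibble::tibble(gene = genes, cell_line = "noise2",
                   expression = base + rnorm(40, sd = 0.1))
  )
  sim <- cellline_similarity(sig, expr)
  expect_identical(sim$cell_line[1], "match")
  expect_gt(sim$similarity[sim$cell_line == "match"], 0.9)
  expect_lt(sim$similarity[sim$cell_line == "inverse"], -0.9)
})

test_that("planted tumor-like lines occupy the top similarity ranks", {
  cfg <- tiny_config(n_screen_lines = 30, n_tumorlike_lines = 5)
  co <- generate_expression_cohort(cfg)
  sig <- build_signature(moderated_ttest(co$matrix), "syn")
  scr <- generate_viability_screen(cfg, co$truth)
  sim <- cellline_similarity(sig, scr$expression)
  expect_setequal(head(sim$cell_line, 5), co$truth$tumorlike_lines)
})

test_that("model-line selection intersects with the consensus or falls back", {
  sims <- tibble::tibble(cell_line = paste0("L", 1:10), n_genes = 40,
                         similarity = seq(1, 0.1, length.out = 10))
  expect_identical(select_model_lines(sims, paste0("L", 1:10), k = 4),
                   paste0("L", 1:4))
  expect_identical(select_model_lines(sims, c("L1", "L3", "L4", "L9"), k = 5),
                   c("L1", "L3", "L4"))
  expect_warning(
    fb <- select_model_lines(sims, c("L9", "L10"), k = 4),
    "falling back"
  )
  expect_identical(fb, paste0("L", 1:4))
})

test_that("dose-response AUC is normalized and matches fine-grid quadrature", {
  doses <- 10 / 4^(0:7)
  flat0 <- tibble::tibble(drug = "d", cell_line = "c", dose_uM = doses,
                          viability_log2fc = 0)
  m0 <- dose_response_metrics(flat0)
  expect_equal(m0$auc, 0)
  expect_equal(m0$low_dose_score, 0)
  flat2 <- dplyr::mutate(flat0, viability_log2fc = -2)
  expect_equal(dose_response_metrics(flat2)$auc, -2)

  # saturated Hill curve (IC50 below the lowest dose)
  ic50 <- 3e-4
  hill <- tibble::tibble(drug = "d", cell_line = "c", dose_uM = doses,
                         viability_log2fc = -2 * doses / (doses + ic50))
  m <- dose_response_metrics(hill)
  expect_lt(m$auc, 0)
  expect_lt(m$auc, m$low_dose_score)  # high doses dominate the average
  # fine-grid numerical integration of the measured (piecewise-linear) curve
  x <- log10(sort(doses)); y <- hill$viability_log2fc[order(hill$dose_uM)]
  f <- approxfun(x, y)
  grid <- seq(min(x), max(x), length.out = 10000)
  oracle <- mean(f(grid))  # Riemann average over the span
  expect_lt(abs(m$auc - oracle), 1e-3)

  # dose-axis rescaling leaves the normalized AUC unchanged
  scaled <- dplyr::mutate(hill, dose_uM = dose_uM * 7.3)
  expect_equal(dose_response_metrics(scaled)$auc, m$auc, tolerance = 1e-12)

  dup <- dplyr::bind_rows(hill, hill[1, ])
  expect_error(dose_response_metrics(dup), "duplicate doses")
})

test_that("biomarker correlation equals the closed-form Pearson oracle", {
  set.seed(31)
  lines <- sprintf("L%02d", 1:20)
  feat <- rnorm(20)
  sens <- -0.5 * feat + rnorm(20, sd = 0.4)
  metrics <- tibble::tibble(drug = "d1", cell_line = lines, n_doses = 8,
                            auc = sens, low_dose_score = sens)
  cn <- tibble::tibble(gene = "G", cell_line = lines, cn = feat)
  out <- biomarker_correlation(metrics, cn = cn, genes = "G")
  r_oracle <- sum((feat - mean(feat)) * (sens - mean(sens))) /
    sqrt(sum((feat - mean(feat))^2) * sum((sens - mean(sens))^2))
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
  expect_identical(out$n, 20L)

  # exact copy of the sensitivity vector: r = 1, p ~ 0
  cn1 <- tibble::tibble(gene = "G", cell_line = lines, cn = sens)
  out1 <- biomarker_correlation(metrics, cn = cn1, genes = "G")
  expect_equal(out1$r, 1, tolerance = 1e-12)
  expect_lt(out1$p, 1e-12)

  # zero-variance feature is flagged, not crashed
  cn0 <- tibble::tibble(gene = "G", cell_line = lines, cn = 1)
  out0 <- biomarker_correlation(metrics, cn = cn0, genes = "G")
  expect_identical(out0$flag, "zero_variance")
  expect_true(is.na(out0$r))
})

test_that("independent features rarely exceed the null correlation band", {
  set.seed(32)
  hits <- vapply(1:200, function(i) {
    x <- rnorm(30); y <- rnorm(30)
    metrics <- tibble::tibble(drug = "d", cell_line = sprintf("L%02d", 1:30),
                              n_doses = 8, auc = y, low_dose_score = y)
    cn <- tibble::tibble(gene = "G", cell_line = sprintf("L%02d", 1:30), cn = x)
    abs(biomarker_correlation(metrics, cn = cn, genes = "G")$r) < 0.36
  }, TRUE)
  expect_gte(mean(hits), 0.93)
})

test_that("segment filtering applies the probe and length thresholds exactly", {
  segs <- tibble::tibble(
    sample = "s1",
    chromosome = "chr1",
    start = c(0, 10, 20, 30, 40, 50) * 1e6,
    end = c(0, 10, 20, 30, 40, 50) * 1e6 +
      c(1e5, 1e5, 1e5, 1e5, 4999999, 5000000),
    probe_count = c(24L, 25L, 49L, 50L, 999L, 999L),
    type = c("loss", "loss", "gain", "gain", "cnLOH", "cnLOH")
  )
  kept <- filter_cn_segments(segs)
  expect_identical(kept$probe_count[kept$type == "loss"], 25L)
  expect_identical(kept$probe_count[kept$type == "gain"], 50L)
  expect_identical(kept$end[kept$type == "cnLOH"] -
                     kept$start[kept$type == "cnLOH"], 5000000)
  # idempotent; retained subset of input; per-type counts conserved
  again <- filter_cn_segments(kept)
  strip <- function(x) { attr(x, "counts") <- NULL; as.data.frame(x) }
  expect_identical(strip(again[names(segs)]), strip(kept[names(segs)]))
  counts <- attr(kept, "counts")
  expect_identical(sum(counts$n_input), nrow(segs))
  bad <- dplyr::mutate(segs[1, ], type = "mystery")
  expect_message(none <- filter_cn_segments(bad), "unknown type")
  expect_identical(nrow(none), 0L)
})

test_that("gene-level calls use maximal overlap with neutral fallbacks", {
  coords <- tibble::tibble(gene = c("G1", "G2"), chromosome = "chr1",
                           start = c(100L, 5000L), end = c(200L, 5100L))
  segs <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2"),
    chromosome = "chr1",
    start = c(50, 90, 120, 120),
    end = c(150, 210, 180, 180),
    probe_count = 100L,
    type = c("loss", "gain", "gain", "loss")
  )
  out <- gene_level_cn_summary(segs, coords, samples = c("s1", "s2", "s3"))
  calls <- out$calls
  # s1/G1: the gain covers the gene fully (overlap 100 vs 50) -> gain
  expect_identical(calls$state[calls$gene == "G1" & calls$sample == "s1"],
                   "gain")
  # s2/G1: contradictory segments with equal overlap -> neutral + flag
  s2row <- calls[calls$gene == "G1" & calls$sample == "s2", ]
  expect_identical(s2row$state, "neutral")
  expect_identical(s2row$flag, "ambiguous")
  # no overlap at all -> neutral
  expect_true(all(calls$state[calls$gene == "G2"] == "neutral"))
  expect_identical(out$frequency$n_altered[out$frequency$gene == "G1"], 1L)
  expect_equal(out$frequency$frequency[out$frequency$gene == "G1"], 1 / 3)
})

test_that("planted biomarker gains yield the expected alteration frequency", {
  cfg <- tiny_config(n_cn_samples = 32, n_biomarker_gains = 8, n_segments = 30)
  segs <- generate_cn_segments(cfg)
  kept <- filter_cn_segments(segs)
  out <- gene_level_cn_summary(kept, synthetic_gene_coords(cfg),
                               samples = sprintf("P%03d", 1:32))
  freq <- out$frequency[out$frequency$gene == cfg$biomarker_gene &
                          out$frequency$type == "gain", ]
  expect_equal(freq$frequency, 0.25)
})

test_that("GISTIC categorization is anchored and monotone", {
  expect_identical(gistic_categorize(1), 0L)    # at ploidy
  expect_identical(gistic_categorize(0), -2L)   # zero copies
  expect_identical(gistic_categorize(c(0.3, 0.8, 1.2, 1.55, 1.56)),
                   c(-1L, 0L, 0L, 1L, 2L))
  expect_error(gistic_categorize(NaN), "finite")
  set.seed(33)
  x <- sort(runif(1000, -0.5, 3))
  expect_true(all(diff(gistic_categorize(x)) >= 0))
})

test_that("dependency summary separates selective from pan-essential genes", {
  lines <- sprintf("L%02d", 1:50)
  pan <- rep(-1, 50)
  set.seed(34)
  selective <- c(rep(-1, 5), rnorm(45, 0, 0.05))
  dep <- rbind(pan = pan, sel = selective)
  colnames(dep) <- lines
  out <- dependency_efficacy_selectivity(dep)
  expect_equal(out$efficacy[out$gene == "pan"], -1)
  expect_equal(out$selectivity[out$gene == "pan"], 0)
  expect_identical(out$flag[out$gene == "pan"], "constant")
  expect_gt(out$selectivity[out$gene == "sel"],
            out$selectivity[out$gene == "pan"])
  # the planted selective gene attains the maximum among 100 genes
  noise <- matrix(rnorm(98 * 50, 0, 0.2), 98, 50,
                  dimnames = list(sprintf("n%02d", 1:98), lines))
  big <- rbind(dep, noise)
  out_big <- dependency_efficacy_selectivity(big)
  expect_identical(out_big$gene[which.max(out_big$selectivity)], "sel")
})
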