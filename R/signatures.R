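#' Select pool samples best matched to a tumor cohort
#'
#' Ranks candidate normal samples (e.g. a GTEx-style pool) by their
#' transcriptional similarity to a tumor cohort and returns the top `k`.
#' Similarity is the median Spearman correlation to the tumor samples
#' computed in a principal-component latent space of the pooled data: both
#' cohorts are projected onto the leading `n_pcs` components of the
#' combined sample set before correlating, which matches on broad
#' expression structure rather than on gene-level noise.  Ties are broken
#' by sample label so the selection is fully deterministic.
#'
#' @param tumors,normal_pool [expression_matrix()] objects sharing at least
#'   500 genes.
#' @param k Number of pool samples to return; `k <=` pool size.
#' @param n_pcs Latent dimensionality (default 20, capped by the data).
#' @return Character vector of `k` pool sample labels, best match first.
#' @export
select_matched_normals <- function(tumors, normal_pool, k, n_pcs = 20) {
  stopifnot(inherits(tumors, "expr_matrix"), inherits(normal_pool, "expr_matrix"))
  k <- check_count(k, "k")
  if (k > ncol(normal_pool$values)) abort("`k` exceeds the pool size")
  shared <- intersect(rownames(tumors$values), rownames(normal_pool$values))
  if (length(shared) < 500) {
    abort(paste0("tumor and pool share only ", length(shared),
                 " genes; at least 500 required"))
  }
  tum <- tumors$values[shared, , drop = FALSE]
  pool <- normal_pool$values[shared, , drop = FALSE]
  combined <- t(cbind(tum, pool))
  n_pcs <- min(n_pcs, nrow(combined) - 1, ncol(combined))
  pc <- prcomp(combined, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  tum_pc <- pc[seq_len(ncol(tum)), , drop = FALSE]
  pool_pc <- pc[ncol(tum) + seq_len(ncol(pool)), , drop = FALSE]
  sim <- apply(pool_pc, 1, function(p) {
    median(apply(tum_pc, 1, function(tv) cor(p, tv, method = "spearman")))
  })
  ord <- order(-sim, colnames(pool))
  colnames(pool)[ord][seq_len(k)]
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NA_real_)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, 0)
}

#' Fit the scaled inverse-chi-square variance prior
#'
#' Estimates the hyperparameters of the hierarchical variance model behind
#' the moderated t-test: gene-wise true variances are assumed drawn from a
#' scaled inverse-chi-square distribution with `d0` prior degrees of
#' freedom and prior value `s0_sq`, so observed sample variances follow
#' `s0_sq` times an F-like distribution.  The fit matches the first two
#' moments of the log sample variances: the spread of `log(s^2)` in excess
#' of the trigamma(df/2) sampling component identifies `d0` (by Newton
#' inversion of the trigamma function), and the mean then identifies
#' `s0_sq`.  When the observed spread is no larger than sampling noise the
#' prior is effectively infinitely informative and `d0 = Inf` is returned
#' with `s0_sq` the (bias-corrected) geometric mean variance.
#'
#' @param sample_variances Per-gene sample variances (>= 50 values, all
#'   positive).
#' @param df_resid Residual degrees of freedom each variance was computed
#'   with (`n_tumor + n_normal - 2` for a two-group design).
#' @return A list of class `variance_prior` with elements `d0` and `s0_sq`.
#' @references Smyth, G.K. (2004) Linear models and empirical Bayes methods
#'   for assessing differential expression in microarray experiments.
#' @export
fit_variance_prior <- function(sample_variances, df_resid) {
  df_resid <- check_count(df_resid, "df_resid")
  s2 <- as.numeric(sample_variances)
  if (length(s2) < 50) abort("need at least 50 gene variances")
  if (any(!is.finite(s2)) || any(s2 <= 0)) {
    abort("all sample variances must be positive and finite")
  }
  z <- log(s2)
  e_correction <- digamma(df_resid / 2) - log(df_resid / 2)
  excess_var <- var(z) - trigamma(df_resid / 2)
  if (excess_var <= 0) {
    prior <- list(d0 = Inf, s0_sq = exp(mean(z) - e_correction))
  } else {
    d0 <- 2 * trigamma_inverse(excess_var)
    s0_sq <- exp(mean(z) - e_correction + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }
  structure(prior, class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat("<variance_prior> d0 = ", format(x$d0, digits = 4),
      ", s0_sq = ", format(x$s0_sq, digits = 4), "\n", sep = "")
  invisible(x)
}

# log2-CPM transform with pseudo-count 0.5, applied internally to counts
# matrices before the moderated t (a documented divergence from a
# negative-binomial count model).
log2_cpm <- function(counts, pseudo = 0.5) {
  lib <- colSums(counts)
  log2(t((t(counts) + pseudo) / (lib + 1)) * 1e6)
}

#' Empirical-Bayes moderated t-test for tumor vs normal
#'
#' Per-gene two-sample comparison with variance moderation: the pooled
#' sample variance of each gene is shrunk toward the prior `s0_sq` with
#' weight `d0` (estimated from the data by [fit_variance_prior()] unless
#' supplied), and the t statistic uses the posterior variance with
#' `d0 + df` degrees of freedom.  `log2FC` is mean(tumor) - mean(normal).
#' Counts matrices are converted to log2-CPM (pseudo-count 0.5)
#' internally.  With `d0 = 0` the statistic reduces to the ordinary
#' pooled-variance t; with `d0 = Inf` it is a z-style test against
#' `s0_sq`.
#'
#' @param m An [expression_matrix()] with at least 2 samples per group.
#' @param prior Optional [fit_variance_prior()] result; fitted from the
#'   data when `NULL`.  Pass `list(d0 = 0)` for the unmoderated test.
#' @return A tibble with one row per input row: `gene`, `mean_expr`,
#'   `log2FC`, `t_mod`, `p`, `padj` (Benjamini-Hochberg), and `flag`
#'   (`"zero_variance"` for degenerate rows reported at `p = 1`).
#' @export
moderated_ttest <- function(m, prior = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  vals <- m$values
  if (m$scale == "counts") vals <- log2_cpm(vals)
  tum <- vals[, m$groups == "tumor", drop = FALSE]
  nrm <- vals[, m$groups == "normal", drop = FALSE]
  n_t <- ncol(tum); n_n <- ncol(nrm)
  if (n_t < 2 || n_n < 2) abort("need at least 2 samples per group")
  df <- n_t + n_n - 2

  mean_t <- rowMeans(tum); mean_n <- rowMeans(nrm)
  ss_t <- rowSums((tum - mean_t)^2)
  ss_n <- rowSums((nrm - mean_n)^2)
  s2 <- (ss_t + ss_n) / df
  lfc <- mean_t - mean_n

  if (is.null(prior)) {
    prior <- fit_variance_prior(pmax(s2, .Machine$double.eps), df)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq %||% 0
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s2_post * (1 / n_t + 1 / n_n))
  t_mod <- lfc / se
  p <- 2 * pt(-abs(t_mod), df = df_total)
  flag <- rep(NA_character_, length(p))
  degenerate <- !is.finite(t_mod)
  if (any(degenerate)) {
    p[degenerate] <- 1
    t_mod[degenerate] <- 0
    flag[degenerate] <- "zero_variance"
  }
  tibble::tibble(
    gene = rownames(vals),
    mean_expr = unname((mean_t * n_t + mean_n * n_n) / (n_t + n_n)),
    log2FC = unname(lfc),
    t_mod = unname(t_mod),
    p = unname(p),
    padj = bh_adjust(unname(p)),
    flag = flag
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' returned in input order.  Thin validating wrapper over
#' [stats::p.adjust()].
#'
#' @param p Numeric p-values in `[0, 1]`; `NaN` is rejected.
#' @return Adjusted p-values, same length and order, all `<= 1`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.nan(p)) || any(is.na(p))) abort("p-values must not be NA/NaN")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Build a disease signature from a differential-expression table
#'
#' Applies the signature cutoffs: up-set `U = {log2FC > lfc_cut, padj <
#' alpha}` and down-set `D = {log2FC < -lfc_cut, padj < alpha}`, defaults
#' |log2FC| > 1 and adjusted p < 0.001.  Duplicate gene labels (multiple
#' probes per symbol) are collapsed first by keeping the row with the
#' lowest raw p-value.
#'
#' @param de Tibble from [moderated_ttest()] (columns `gene`, `log2FC`,
#'   `p`, `padj` required).
#' @param dataset_id Label identifying the dataset.
#' @param lfc_cut,alpha Signature cutoffs.
#' @return A `disease_signature`: list with `dataset_id`, `up`, `down`
#'   (character vectors) and `table` (the collapsed DE tibble).  A warning
#'   is raised when both sets are empty.
#' @export
build_signature <- function(de, dataset_id, lfc_cut = 1, alpha = 0.001) {
  stopifnot(is.data.frame(de), nrow(de) > 0)
  need <- c("gene", "log2FC", "p", "padj")
  if (!all(need %in% names(de))) {
    abort(paste0("`de` must contain columns ", paste(need, collapse = ", ")))
  }
  collapsed <- de |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  up <- collapsed$gene[collapsed$log2FC > lfc_cut & collapsed$padj < alpha]
  down <- collapsed$gene[collapsed$log2FC < -lfc_cut & collapsed$padj < alpha]
  if (length(up) == 0 && length(down) == 0) {
    warn(paste0("signature '", dataset_id,
                "' has empty up and down sets at the given cutoffs"))
  }
  structure(
    list(dataset_id = dataset_id, up = sort(up), down = sort(down),
         table = collapsed, lfc_cut = lfc_cut, alpha = alpha),
    class = "disease_signature"
  )
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("<disease_signature> ", x$dataset_id, ": ", length(x$up), " up / ",
      length(x$down), " down of ", nrow(x$table), " genes (|log2FC| > ",
      x$lfc_cut, ", padj < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Intersect disease signatures across datasets
#'
#' Summarizes how signatures overlap: pairwise intersection counts of the
#' combined (up or down) memberships, the count of genes shared by exactly
#' k signatures, the set shared by all, and a top-DEG ranking of the
#' shared-by-all genes by the L1 norm of their |log2FC| vector across
#' signatures (largest first).
#'
#' @param sigs List of >= 2 [build_signature()] results with unique
#'   dataset ids.
#' @return A `signature_overlap`: list with `pairwise` (tibble `a`, `b`,
#'   `n_shared`), `k_way` (tibble `k`, `n_genes`), `shared_all` (character)
#'   and `top_deg` (tibble `gene`, `l1_lfc`, sorted descending).
#' @export
intersect_signatures <- function(sigs) {
  if (length(sigs) < 2) abort("need at least 2 signatures")
  ids <- vapply(sigs, function(s) s$dataset_id, "")
  if (anyDuplicated(ids)) abort("duplicate dataset_ids")
  members <- lapply(sigs, function(s) union(s$up, s$down))
  names(members) <- ids

  pairs <- utils::combn(ids, 2)
  pairwise <- tibble::tibble(
    a = pairs[1, ], b = pairs[2, ],
    n_shared = apply(pairs, 2, function(pr) {
      length(intersect(members[[pr[1]]], members[[pr[2]]]))
    })
  )
  all_genes <- unlist(members, use.names = FALSE)
  counts <- table(all_genes)
  k_way <- tibble::tibble(k = as.integer(names(table(counts))),
                          n_genes = as.integer(table(counts)))
  shared_all <- sort(names(counts)[counts == length(sigs)])

  l1 <- vapply(shared_all, function(g) {
    sum(vapply(sigs, function(s) {
      abs(s$table$log2FC[match(g, s$table$gene)])
    }, 0))
  }, 0)
  top_deg <- tibble::tibble(gene = shared_all, l1_lfc = unname(l1)) |>
    dplyr::arrange(dplyr::desc(.data$l1_lfc), .data$gene)
  structure(
    list(pairwise = pairwise, k_way = k_way, shared_all = shared_all,
         top_deg = top_deg, n_signatures = length(sigs)),
    class = "signature_overlap"
  )
}

#' @export
print.signature_overlap <- function(x, ...) {
  cat("<signature_overlap> ", x$n_signatures, " signatures; ",
      length(x$shared_all), " genes shared by all\n", sep = "")
  invisible(x)
}
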