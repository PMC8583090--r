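#' Transcriptional similarity of cell lines to a disease signature
#'
#' For each line, the Spearman correlation between the signature's log2
#' fold changes and the line's differential expression (its expression
#' minus the per-gene median across all lines), restricted to the
#' signature's up/down genes.  Lines sharing fewer than 10 signature genes
#' are skipped with a warning.
#'
#' @param sig A [build_signature()] result.
#' @param expression Tibble `gene`, `cell_line`, `expression`
#'   (log2(TPM+1)).
#' @return Tibble `cell_line`, `n_genes`, `similarity`, sorted by
#'   decreasing similarity (ties broken by line label).
#' @export
cellline_similarity <- function(sig, expression) {
  stopifnot(inherits(sig, "disease_signature"), is.data.frame(expression))
  sig_genes <- union(sig$up, sig$down)
  lfc <- sig$table$log2FC[match(sig_genes, sig$table$gene)]
  names(lfc) <- sig_genes
  wide <- expression |>
    dplyr::filter(.data$gene %in% sig_genes) |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "expression")
  if (nrow(wide) == 0) abort("no signature genes present in the line expression")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$gene
  diff <- mat - apply(mat, 1, median)
  res <- purrr::map_dfr(colnames(diff), function(cl) {
    ok <- is.finite(diff[, cl])
    if (sum(ok) < 10) {
      warn(paste0("cell line '", cl, "' shares < 10 signature genes; skipped"))
      return(tibble::tibble())
    }
    tibble::tibble(
      cell_line = cl, n_genes = sum(ok),
      similarity = cor(diff[ok, cl], lfc[rownames(diff)][ok],
                       method = "spearman")
    )
  })
  dplyr::arrange(res, dplyr::desc(.data$similarity), .data$cell_line)
}

#' Build a cell-line gene-set library from line expression
#'
#' One set per line containing its `top_n` most over-expressed genes
#' relative to the panel median, over the universe of profiled genes.
#' Querying a disease signature against this library and taking the
#' consensus mirrors matching tumor signatures to model lines through
#' line-labelled enrichment terms.
#'
#' @param expression Tibble `gene`, `cell_line`, `expression`.
#' @param top_n Genes per line set (default 50).
#' @return A [geneset_library()] whose term names are cell-line labels.
#' @export
cellline_geneset_library <- function(expression, top_n = 50) {
  stopifnot(is.data.frame(expression))
  wide <- tidyr::pivot_wider(expression, names_from = "cell_line",
                             values_from = "expression")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$gene
  diff <- mat - apply(mat, 1, median)
  sets <- lapply(colnames(diff), function(cl) {
    rownames(diff)[order(-diff[, cl])][seq_len(min(top_n, nrow(diff)))]
  })
  names(sets) <- colnames(diff)
  geneset_library("cell_lines", sets, rownames(mat))
}

#' Select model cell lines
#'
#' Intersects the `k` most signature-similar lines with the lines named by
#' the cell-line consensus list; if fewer than 3 lines survive the
#' intersection, falls back to the top-`k` similarity ranking with a
#' warning.
#'
#' @param similarities Tibble from [cellline_similarity()].
#' @param consensus A [build_consensus_list()] whose terms are cell-line
#'   labels, or a character vector of line labels.
#' @param k Number of similarity-ranked lines considered.
#' @return Character vector of selected line labels.
#' @export
select_model_lines <- function(similarities, consensus, k) {
  stopifnot(is.data.frame(similarities), nrow(similarities) > 0)
  k <- check_count(k, "k")
  lines <- if (inherits(consensus, "consensus_list")) consensus$terms
           else as.character(consensus)
  top <- head(similarities$cell_line, k)
  sel <- intersect(top, lines)
  if (length(sel) < 3) {
    warn("fewer than 3 lines in the consensus intersection; falling back to top-k similarity")
    sel <- top
  }
  sel
}

#' Dose-response sensitivity metrics
#'
#' Summarizes each drug x cell line viability curve: `auc` is the
#' trapezoidal area of viability log2FC over log10 dose divided by the
#' log10-dose span (so a flat curve at value v scores v, and rescaling the
#' dose axis leaves it unchanged), and `low_dose_score` is the mean
#' viability at the `n_low` smallest doses.
#'
#' @param curves Tibble `drug`, `cell_line`, `dose_uM`,
#'   `viability_log2fc`; doses must be unique and positive within a curve.
#' @param n_low Number of lowest doses defining the low-dose score
#'   (default 3, about <= 0.16 uM on the default 8-point ladder).
#' @return Tibble `drug`, `cell_line`, `n_doses`, `auc`,
#'   `low_dose_score`.
#' @export
dose_response_metrics <- function(curves, n_low = 3) {
  stopifnot(is.data.frame(curves))
  need <- c("drug", "cell_line", "dose_uM", "viability_log2fc")
  if (!all(need %in% names(curves))) {
    abort(paste0("curves must contain columns ", paste(need, collapse = ", ")))
  }
  if (any(curves$dose_uM <= 0)) abort("doses must be positive")
  curves |>
    dplyr::group_by(.data$drug, .data$cell_line) |>
    dplyr::group_modify(function(df, key) {
      if (anyDuplicated(df$dose_uM)) {
        abort(paste0("duplicate doses in curve ", key$drug, " / ", key$cell_line))
      }
      if (nrow(df) < 2) abort("curves need at least 2 dose points")
      df <- dplyr::arrange(df, .data$dose_uM)
      x <- log10(df$dose_uM)
      y <- df$viability_log2fc
      auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2) / (max(x) - min(x))
      tibble::tibble(
        n_doses = nrow(df),
        auc = auc,
        low_dose_score = mean(head(y, min(n_low, nrow(df))))
      )
    }) |>
    dplyr::ungroup()
}

#' Correlate biomarker copy number / expression with drug sensitivity
#'
#' For each requested gene, feature modality (copy number and expression)
#' and drug, the Pearson correlation across cell lines between the feature
#' value and the sensitivity metric, with the two-sided t-based p-value.
#' Zero-variance features yield an `NA` correlation flagged in the output.
#'
#' @param metrics Tibble from [dose_response_metrics()].
#' @param cn Tibble `gene`, `cell_line`, `cn` (log2(relative to
#'   ploidy + 1)); may be `NULL`.
#' @param expression Tibble `gene`, `cell_line`, `expression`
#'   (log2(TPM+1)); may be `NULL`.
#' @param genes Genes to test.
#' @param metric Which sensitivity column to correlate (default
#'   `"auc"`; any numeric column of `metrics`).
#' @return Tibble `gene`, `modality`, `drug`, `r`, `p`, `n`, `flag`.
#' @export
biomarker_correlation <- function(metrics, cn = NULL, expression = NULL,
                                  genes, metric = "auc") {
  stopifnot(is.data.frame(metrics))
  if (!metric %in% names(metrics)) {
    abort(paste0("metric column '", metric, "' not found"))
  }
  feats <- dplyr::bind_rows(
    if (!is.null(cn)) dplyr::transmute(cn, gene = .data$gene,
                                       cell_line = .data$cell_line,
                                       modality = "cn", value = .data$cn),
    if (!is.null(expression)) dplyr::transmute(expression, gene = .data$gene,
                                               cell_line = .data$cell_line,
                                               modality = "expression",
                                               value = .data$expression)
  )
  if (is.null(feats) || nrow(feats) == 0) abort("no feature tables supplied")
  feats <- dplyr::filter(feats, .data$gene %in% genes)
  joined <- dplyr::inner_join(
    feats,
    dplyr::select(metrics, "drug", "cell_line", sens = dplyr::all_of(metric)),
    by = "cell_line", relationship = "many-to-many"
  )
  joined |>
    dplyr::group_by(.data$gene, .data$modality, .data$drug) |>
    dplyr::group_modify(function(df, key) {
      n <- sum(complete.cases(df$value, df$sens))
      if (n < 3) abort("fewer than 3 shared lines for a correlation")
      if (sd(df$value) == 0 || sd(df$sens) == 0) {
        return(tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                              flag = "zero_variance"))
      }
      ct <- cor.test(df$value, df$sens, method = "pearson")
      tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
                     flag = NA_character_)
    }) |>
    dplyr::ungroup()
}

#' Dependency efficacy and selectivity
#'
#' Collapses a gene x cell-line dependency-score matrix (more negative =
#' stronger growth reduction on knockout) to two axes per gene: `efficacy`
#' is the 10th percentile of the gene's scores (how strong the effect is
#' where it is strongest) and `selectivity` is the gap between the median
#' and that percentile scaled by the MAD-based robust spread (how
#' concentrated the effect is in a subset of lines).  Pan-essential genes
#' score high efficacy but near-zero selectivity; genes lethal in a small
#' subset score high on both.
#'
#' @param dep Numeric matrix, genes in rows, cell lines in columns (>= 10
#'   lines), or a tibble `gene`, `cell_line`, `score`.
#' @param probs Lower quantile defining efficacy (default 0.1).
#' @param eps Spread floor guarding against division by zero.
#' @return Tibble `gene`, `efficacy`, `selectivity`, `flag`
#'   (`"constant"` for zero-spread rows, whose selectivity is 0).
#' @export
dependency_efficacy_selectivity <- function(dep, probs = 0.1, eps = 1e-8) {
  if (is.data.frame(dep)) {
    wide <- tidyr::pivot_wider(dep, names_from = "cell_line",
                               values_from = "score")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    rownames(mat) <- wide$gene
    dep <- mat
  }
  stopifnot(is.matrix(dep), is.numeric(dep))
  if (ncol(dep) < 10) abort("need at least 10 cell lines per gene")
  purrr::map_dfr(rownames(dep) %||% as.character(seq_len(nrow(dep))),
                 function(g) {
    x <- dep[g, ]
    q <- unname(quantile(x, probs))
    spread <- mad(x)  # already scaled by 1.4826
    constant <- spread == 0 && median(x) == q
    tibble::tibble(
      gene = g,
      efficacy = q,
      selectivity = if (constant) 0 else (median(x) - q) / (spread + eps),
      flag = if (spread == 0) "constant" else NA_character_
    )
  })
}
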