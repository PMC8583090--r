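#' Construct a gene-set library
#'
#' A named collection of gene sets over an explicit background universe.
#' The universe must be supplied rather than inferred: over-representation
#' p-values depend on it directly.
#'
#' @param name Library label.
#' @param sets Named list of character vectors; every set must be
#'   non-empty and contained in `universe`.
#' @param universe Character vector of background genes.
#' @return A `geneset_library`.
#' @export
geneset_library <- function(name, sets, universe) {
  if (length(sets) == 0 || is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a non-empty uniquely named list")
  }
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) abort(paste0("set '", nm, "' is empty"))
    if (!all(sets[[nm]] %in% universe)) {
      abort(paste0("set '", nm, "' contains genes outside the universe"))
    }
  }
  structure(list(name = name, sets = sets, universe = universe),
            class = "geneset_library")
}

#' @export
print.geneset_library <- function(x, ...) {
  cat("<geneset_library> '", x$name, "': ", length(x$sets), " sets over ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

# Hypergeometric upper tail at the observed overlap (one-sided Fisher
# exact): P(X >= k) with K set genes among N, drawing n query genes.
hyper_upper_tail <- function(k, set_size, universe_size, query_size) {
  phyper(k - 1, set_size, universe_size - set_size, query_size,
         lower.tail = FALSE)
}

#' Over-representation test of a query against a gene-set library
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per term on the
#' 2x2 membership table of query vs term within the library universe, with
#' Benjamini-Hochberg adjustment across the library's terms.  Query genes
#' outside the universe are dropped with a message.
#'
#' @param query Character vector of genes.
#' @param library A [geneset_library()].
#' @return A tibble per term: `term`, `overlap_count`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `padj`.
#' @export
overrepresentation_test <- function(query, library) {
  stopifnot(inherits(library, "geneset_library"))
  query <- unique(as.character(query))
  dropped <- sum(!query %in% library$universe)
  if (dropped > 0) {
    inform(paste0(dropped, " query gene(s) outside the library universe dropped"))
  }
  query <- intersect(query, library$universe)
  if (length(query) == 0) abort("query is empty after restricting to the universe")
  n_u <- length(library$universe)
  n_q <- length(query)
  res <- purrr::imap_dfr(library$sets, function(set, term) {
    k <- length(intersect(query, set))
    tibble::tibble(
      term = term, overlap_count = k, set_size = length(set),
      query_size = n_q, universe_size = n_u,
      p = hyper_upper_tail(k, length(set), n_u, n_q)
    )
  })
  res$padj <- bh_adjust(res$p)
  res
}

#' Permutation null of term ranks for the combined score
#'
#' Draws random query sets of a matched size from the library universe,
#' runs the over-representation test on each, and records the mean and
#' standard deviation of every term's rank (rank 1 = most enriched, ties
#' averaged).  This explicit null replaces the rank-correction used by
#' combined-score web tools with a reproducible, seeded equivalent.
#'
#' @param library A [geneset_library()].
#' @param query_size Size of the random queries.
#' @param n_null Number of random queries (>= 100).
#' @param seed RNG seed.
#' @return A tibble: `term`, `mean_rank`, `sd_rank`.
#' @export
null_rank_summary <- function(library, query_size, n_null = 200, seed = 0) {
  stopifnot(inherits(library, "geneset_library"))
  if (n_null < 100) abort("`n_null` must be at least 100")
  n_u <- length(library$universe)
  query_size <- min(check_count(query_size, "query_size"), n_u - 1)
  # term x gene indicator for fast overlap counting
  terms <- names(library$sets)
  memb <- matrix(FALSE, length(terms), n_u,
                 dimnames = list(terms, library$universe))
  for (tm in terms) memb[tm, library$sets[[tm]]] <- TRUE
  set_sizes <- rowSums(memb)
  set.seed(seed)
  ranks <- matrix(NA_real_, length(terms), n_null)
  for (b in seq_len(n_null)) {
    q <- sample.int(n_u, query_size)
    k <- rowSums(memb[, q, drop = FALSE])
    p <- hyper_upper_tail(k, set_sizes, n_u, query_size)
    ranks[, b] <- rank(p, ties.method = "average")
  }
  tibble::tibble(
    term = terms,
    mean_rank = rowMeans(ranks),
    sd_rank = apply(ranks, 1, sd)
  )
}

#' Combined enrichment score
#'
#' Adds the rank-deviation z-score and the combined score to an
#' over-representation result: `z = (mean null rank - observed rank) / sd`
#' (positive = ranked better than under the null) and
#' `combined = -ln(p) * z`, which is 0 at `p = 1` regardless of z and
#' increases with enrichment for fixed z.  Terms whose null rank is
#' degenerate (zero spread) get `z = 0` with a warning.
#'
#' @param records Tibble from [overrepresentation_test()].
#' @param null_summary Tibble from [null_rank_summary()] on the same
#'   library.
#' @return `records` with added columns `rank`, `z`, `combined`, sorted by
#'   decreasing `combined`.
#' @export
combined_score <- function(records, null_summary) {
  stopifnot(is.data.frame(records), is.data.frame(null_summary))
  obs_rank <- rank(records$p, ties.method = "average")
  m <- match(records$term, null_summary$term)
  if (anyNA(m)) abort("null summary is missing terms present in `records`")
  mean_rank <- null_summary$mean_rank[m]
  sd_rank <- null_summary$sd_rank[m]
  degenerate <- !is.finite(sd_rank) | sd_rank == 0
  if (any(degenerate)) {
    warn(paste0(sum(degenerate), " term(s) have zero null-rank spread; z set to 0"))
  }
  z <- ifelse(degenerate, 0, (mean_rank - obs_rank) / sd_rank)
  records |>
    dplyr::mutate(rank = obs_rank, z = z,
                  combined = -log(.data$p) * z) |>
    dplyr::arrange(dplyr::desc(.data$combined))
}

#' Enrichment of a query with combined scores, in one call
#'
#' Convenience wrapper chaining [overrepresentation_test()],
#' [null_rank_summary()] and [combined_score()].
#'
#' @inheritParams overrepresentation_test
#' @inheritParams null_rank_summary
#' @return Tibble as from [combined_score()].
#' @export
enrich_query <- function(query, library, n_null = 200, seed = 0) {
  records <- overrepresentation_test(query, library)
  nulls <- null_rank_summary(library, query_size = records$query_size[1],
                             n_null = n_null, seed = seed)
  combined_score(records, nulls)
}

#' Build a consensus list of enrichment terms across signatures
#'
#' Takes the per-signature enrichment results for one library and keeps
#' each signature's top `k` terms by combined score, retaining a term only
#' if it is over-represented (adjusted p below `alpha`) in at least one
#' signature.  With `k = 5` this is the pathway/term consensus; `k = 20`
#' gives the cell-line consensus variant used for model-line matching.
#'
#' @param per_signature_results Tibble with columns `signature`, `term`,
#'   `combined`, `padj` (e.g. several [enrich_query()] results bound
#'   together with a `signature` column).
#' @param k Top terms taken per signature (default 5).
#' @param alpha Over-representation cutoff on adjusted p (default 0.05).
#' @return A `consensus_list`: list with `terms` (included terms),
#'   `table` (the long per-signature rows for included terms, with
#'   `inclusion_flag`), and `scores` (wide term x signature tibble of
#'   combined scores for heatmap export).
#' @export
build_consensus_list <- function(per_signature_results, k = 5, alpha = 0.05) {
  stopifnot(is.data.frame(per_signature_results))
  need <- c("signature", "term", "combined", "padj")
  if (!all(need %in% names(per_signature_results))) {
    abort(paste0("results must contain columns ", paste(need, collapse = ", ")))
  }
  res <- per_signature_results
  top_terms <- res |>
    dplyr::group_by(.data$signature) |>
    dplyr::slice_max(.data$combined, n = k, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$term) |>
    unique()
  significant <- res |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(min_padj = min(.data$padj), .groups = "drop") |>
    dplyr::filter(.data$min_padj < alpha) |>
    dplyr::pull(.data$term)
  included <- sort(intersect(top_terms, significant))
  table <- res |>
    dplyr::mutate(inclusion_flag = .data$term %in% included)
  scores <- res |>
    dplyr::filter(.data$term %in% included) |>
    dplyr::select("term", "signature", "combined") |>
    tidyr::pivot_wider(names_from = "signature", values_from = "combined")
  structure(list(terms = included, table = table, scores = scores,
                 k = k, alpha = alpha),
            class = "consensus_list")
}

#' @export
print.consensus_list <- function(x, ...) {
  cat("<consensus_list> ", length(x$terms), " terms (top-", x$k,
      " per signature, padj < ", x$alpha, " in >= 1 signature)\n", sep = "")
  invisible(x)
}
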