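# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a disease signature
#'
#' @param x A [build_signature()] result.
#' @param ... Unused.
#' @return The collapsed differential-expression tibble with `dataset_id`
#'   and a `direction` column (`up` / `down` / `ns`).
#' @export
tidy.disease_signature <- function(x, ...) {
  x$table |>
    dplyr::mutate(
      dataset_id = x$dataset_id,
      direction = dplyr::case_when(
        .data$gene %in% x$up ~ "up",
        .data$gene %in% x$down ~ "down",
        TRUE ~ "ns"
      )
    ) |>
    dplyr::relocate("dataset_id")
}

#' @rdname tidy.disease_signature
#' @export
glance.disease_signature <- function(x, ...) {
  tibble::tibble(dataset_id = x$dataset_id, n_genes = nrow(x$table),
                 n_up = length(x$up), n_down = length(x$down),
                 lfc_cut = x$lfc_cut, alpha = x$alpha)
}

#' Tidy a signature overlap summary
#'
#' @param x An [intersect_signatures()] result.
#' @param ... Unused.
#' @return The pairwise intersection counts tibble.
#' @export
tidy.signature_overlap <- function(x, ...) x$pairwise

#' @rdname tidy.signature_overlap
#' @export
glance.signature_overlap <- function(x, ...) {
  tibble::tibble(n_signatures = x$n_signatures,
                 n_shared_all = length(x$shared_all))
}

#' Tidy a variance prior
#'
#' @param x A [fit_variance_prior()] result.
#' @param ... Unused.
#' @return One-row tibble with `d0` and `s0_sq`.
#' @export
tidy.variance_prior <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq)
}

#' Tidy a consensus list
#'
#' @param x A [build_consensus_list()] result.
#' @param ... Unused.
#' @return The long per-signature table restricted to included terms.
#' @export
tidy.consensus_list <- function(x, ...) {
  dplyr::filter(x$table, .data$inclusion_flag)
}

#' @rdname tidy.consensus_list
#' @export
glance.consensus_list <- function(x, ...) {
  tibble::tibble(n_terms = length(x$terms), k = x$k, alpha = x$alpha)
}
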