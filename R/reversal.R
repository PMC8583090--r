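#' Connectivity-style enrichment score of a gene set in a ranked profile
#'
#' Weighted-threshold Kolmogorov-Smirnov statistic with equal gene weights,
#' the building block of the reversal score.  With the hit positions
#' `p_1 < ... < p_s` of the set in a ranking of `N` genes (most
#' up-regulated first), the score is `a = max_j(j/s - p_j/N)` when
#' `a >= b`, else `-b` with `b = max_j(p_j/N - (j-1)/s)`.  A positive
#' score means the set is concentrated at the top of the ranking (induced
#' by the perturbation), a negative one that it sits at the bottom
#' (repressed).
#'
#' @param set_s Character vector of genes; members absent from the ranking
#'   are dropped (intersection semantics), and an error is raised if none
#'   remain or if the set covers the whole ranking.
#' @param ranking Character vector: the profile's genes ordered from most
#'   up- to most down-regulated.
#' @return A single score in `[-1, 1]`.
#' @export
enrichment_score <- function(set_s, ranking) {
  n <- length(ranking)
  pos <- sort(match(set_s, ranking))
  pos <- pos[!is.na(pos)]
  s <- length(pos)
  if (s == 0) abort("gene set has empty intersection with the profile universe")
  if (s >= n) abort("gene set must be a strict subset of the profile universe")
  j <- seq_len(s)
  a <- max(j / s - pos / n)
  b <- max(pos / n - (j - 1) / s)
  if (a >= b) a else -b
}

#' Reversal gene expression score (RGES) of one profile against a signature
#'
#' Scores how a drug-induced profile relates to a disease signature: the
#' enrichment scores of the signature's up-set and down-set in the
#' profile's ranking are combined as `rges = es_up - es_down` when the two
#' have opposite signs (or either is zero), and 0 otherwise.  Negative
#' RGES means reversal -- the disease's up-genes are repressed by the drug
#' and its down-genes induced; positive RGES means the profile mimics the
#' disease.
#'
#' @param sig A [build_signature()] result with non-empty up and down sets
#'   (after intersection with the profile universe).
#' @param ranking Profile gene ranking, most up-regulated first.
#' @return A one-row tibble: `es_up`, `es_down`, `rges`.
#' @export
compute_rges <- function(sig, ranking) {
  stopifnot(inherits(sig, "disease_signature"))
  es_up <- enrichment_score(sig$up, ranking)
  es_down <- enrichment_score(sig$down, ranking)
  rges <- if (es_up * es_down <= 0) es_up - es_down else 0
  tibble::tibble(es_up = es_up, es_down = es_down, rges = rges)
}

#' Score every profile of a perturbation library against a signature
#'
#' Ranks each drug x cell line x dose x time profile by its differential
#' values (most up-regulated first) and computes its RGES against the
#' signature.
#'
#' @param sig A [build_signature()] result.
#' @param library_tbl Long-format perturbation library: columns `drug`,
#'   `cell_line`, `dose_uM`, `time_h`, `gene`, `value`.
#' @return A tibble with one row per profile: `drug`, `cell_line`,
#'   `dose_uM`, `time_h`, `n_genes`, `es_up`, `es_down`, `rges`.
#' @export
compute_rges_table <- function(sig, library_tbl) {
  stopifnot(inherits(sig, "disease_signature"), is.data.frame(library_tbl))
  need <- c("drug", "cell_line", "dose_uM", "time_h", "gene", "value")
  if (!all(need %in% names(library_tbl))) {
    abort(paste0("library must contain columns ", paste(need, collapse = ", ")))
  }
  library_tbl |>
    dplyr::group_by(.data$drug, .data$cell_line, .data$dose_uM, .data$time_h) |>
    dplyr::group_modify(function(df, key) {
      ranking <- df$gene[order(-df$value)]
      dplyr::bind_cols(tibble::tibble(n_genes = length(ranking)),
                       compute_rges(sig, ranking))
    }) |>
    dplyr::ungroup()
}

#' Estimate dose and time score offsets relative to the reference condition
#'
#' The library's reference condition is 10 uM / 24 h.  For drugs observed
#' both at the reference and at a lower dose (same reference time), the
#' dose offset `alpha` is the median across drugs of mean RGES at
#' non-reference dose minus mean RGES at reference; `beta` is the analogous
#' time offset.  Profiles measured away from the reference are later
#' shifted by these offsets before summarization, removing the systematic
#' score bias of weaker conditions.
#'
#' @param records RGES table from [compute_rges_table()].
#' @param ref_dose,ref_time Reference condition (defaults 10 uM, 24 h).
#' @return Named numeric `c(alpha = , beta = )`; `(0, 0)` with a warning
#'   when the library has no paired reference/non-reference observations.
#' @export
estimate_dose_time_offsets <- function(records, ref_dose = 10, ref_time = 24) {
  stopifnot(is.data.frame(records))
  is_ref_dose <- records$dose_uM >= ref_dose
  is_ref_time <- records$time_h >= ref_time
  per_drug <- function(keep_ref, keep_non) {
    ref <- records[keep_ref, ] |>
      dplyr::group_by(.data$drug) |>
      dplyr::summarise(ref_rges = mean(.data$rges), .groups = "drop")
    non <- records[keep_non, ] |>
      dplyr::group_by(.data$drug) |>
      dplyr::summarise(non_rges = mean(.data$rges), .groups = "drop")
    both <- dplyr::inner_join(ref, non, by = "drug")
    if (nrow(both) == 0) return(NA_real_)
    median(both$non_rges - both$ref_rges)
  }
  alpha <- per_drug(is_ref_dose & is_ref_time, !is_ref_dose & is_ref_time)
  beta <- per_drug(is_ref_dose & is_ref_time, is_ref_dose & !is_ref_time)
  if (is.na(alpha) && is.na(beta)) {
    warn("no paired reference/non-reference profiles; offsets set to 0")
  }
  c(alpha = alpha %|NA|% 0, beta = beta %|NA|% 0)
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Summarize RGES across a drug's profiles (sRGES)
#'
#' Adjusts each profile's RGES to the reference condition (subtracting the
#' dose offset for low-dose profiles and the time offset for short-time
#' profiles) and averages the adjusted scores per drug with cell-line
#' similarity weights.  `n_strong` counts the drug's profiles whose raw
#' RGES falls below the strong-reversal threshold (-0.25).
#'
#' @param records RGES table from [compute_rges_table()].
#' @param similarity Optional named numeric of cell-line weights; missing
#'   lines weigh 1, negative values are clamped to 0.  All-zero weights
#'   fall back to uniform with a warning.
#' @param offsets Named `c(alpha, beta)` from
#'   [estimate_dose_time_offsets()]; default no adjustment.
#' @param strong_cut Raw-RGES threshold defining a strong profile.
#' @param ref_dose,ref_time Reference condition.
#' @return A tibble per drug: `drug`, `srges`, `n_profiles`, `n_strong`,
#'   sorted ascending by `srges`.
#' @export
summarize_srges <- function(records, similarity = NULL,
                            offsets = c(alpha = 0, beta = 0),
                            strong_cut = -0.25, ref_dose = 10, ref_time = 24) {
  stopifnot(is.data.frame(records))
  if (is.null(names(offsets))) {
    names(offsets) <- c("alpha", "beta")[seq_along(offsets)]
  }
  alpha <- unname(offsets["alpha"] %|NA|% 0)
  beta <- unname(offsets["beta"] %|NA|% 0)
  w <- rep(1, nrow(records))
  if (!is.null(similarity)) {
    if (is.null(names(similarity))) abort("`similarity` must be named by cell line")
    matched <- similarity[records$cell_line]
    w <- ifelse(is.na(matched), 1, pmax(matched, 0))
  }
  if (all(w == 0)) {
    warn("all similarity weights are zero; falling back to uniform weights")
    w <- rep(1, nrow(records))
  }
  records |>
    dplyr::mutate(
      .adj = .data$rges - alpha * (.data$dose_uM < ref_dose) -
        beta * (.data$time_h < ref_time),
      .w = w
    ) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      srges = sum(.data$.w * .data$.adj) / sum(.data$.w),
      n_profiles = dplyr::n(),
      n_strong = sum(.data$rges < strong_cut),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$srges)
}

#' Select candidate reversal drugs
#'
#' Applies the candidate rule: keep drugs with `srges < srges_cut` (default
#' -0.25) supported by at least `n_strong_min` (default 3, i.e. more than
#' two) strong profiles, sort ascending by sRGES and keep the `top_n`.
#' When the table spans several signatures (a `signature` column), a drug
#' appearing for more than one signature is included once, keeping its
#' lowest sRGES.
#'
#' @param srges_tbl Tibble from [summarize_srges()], optionally with a
#'   `signature` column.
#' @param top_n Maximum candidates returned (default 100).
#' @param srges_cut sRGES threshold (default -0.25).
#' @param n_strong_min Minimum number of strong profiles (default 3).
#' @return A tibble of candidates with a dense ascending `rank` column;
#'   may be empty.
#' @export
select_candidates <- function(srges_tbl, top_n = 100, srges_cut = -0.25,
                              n_strong_min = 3) {
  stopifnot(is.data.frame(srges_tbl), nrow(srges_tbl) > 0)
  out <- srges_tbl |>
    dplyr::filter(.data$srges < srges_cut, .data$n_strong >= n_strong_min) |>
    dplyr::arrange(.data$srges)
  if ("signature" %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data$drug) |>
      dplyr::slice_min(.data$srges, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$srges)
  }
  out <- head(out, top_n)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Aggregate candidates by mechanism of action and target
#'
#' Counts selected candidates per annotated mechanism of action, and per
#' target gene keeping only targets shared by at least two drugs.
#' Candidates without an annotation are grouped under `"unknown"`.
#'
#' @param candidates Tibble from [select_candidates()].
#' @param annotations Tibble with columns `drug`, `moa`, `targets`
#'   (comma-separated gene labels or a list column), `clinical_phase`
#'   (optional).
#' @return A list of tibbles `moa` (`moa`, `n_drugs`) and `targets`
#'   (`target`, `n_drugs`, only targets with `n_drugs >= 2`).
#' @export
aggregate_moa <- function(candidates, annotations) {
  stopifnot(is.data.frame(candidates))
  ann <- candidates |>
    dplyr::left_join(annotations, by = "drug")
  moa <- ann |>
    dplyr::mutate(moa = dplyr::coalesce(.data$moa, "unknown")) |>
    dplyr::count(.data$moa, name = "n_drugs") |>
    dplyr::arrange(dplyr::desc(.data$n_drugs), .data$moa)
  tg <- ann
  if (!is.list(tg$targets)) {
    tg$targets <- strsplit(as.character(tg$targets %||% ""), ",\\s*")
  }
  targets <- tg |>
    dplyr::select("drug", "targets") |>
    tidyr::unnest("targets") |>
    dplyr::filter(!is.na(.data$targets), .data$targets != "") |>
    dplyr::distinct(.data$drug, .data$targets) |>
    dplyr::count(target = .data$targets, name = "n_drugs") |>
    dplyr::filter(.data$n_drugs >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_drugs), .data$target)
  list(moa = moa, targets = targets)
}
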