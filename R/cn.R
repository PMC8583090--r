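#' Filter copy-number segments by probe-count and length criteria
#'
#' Retains losses supported by at least `probes_loss` probes, gains by at
#' least `probes_gain` probes, and copy-neutral LOH segments spanning at
#' least `cnloh_mb` megabases; everything else is dropped.  Rows with an
#' unknown type are rejected (dropped with a message).  Defaults are the
#' array-analysis retention thresholds: 25 probes for losses, 50 for
#' gains, 5 Mb for cnLOH.
#'
#' @param segments Tibble with columns `chromosome`, `start`, `end`
#'   (0-based half-open bp), `probe_count`, `type` (`gain` / `loss` /
#'   `cnLOH`); extra columns (e.g. `sample`) pass through.
#' @param probes_loss,probes_gain,cnloh_mb Retention thresholds.
#' @return The retained rows, with a `counts` attribute tabulating
#'   input/retained rows per type.
#' @export
filter_cn_segments <- function(segments, probes_loss = 25, probes_gain = 50,
                               cnloh_mb = 5) {
  stopifnot(is.data.frame(segments))
  need <- c("chromosome", "start", "end", "probe_count", "type")
  if (!all(need %in% names(segments))) {
    abort(paste0("segments must contain columns ", paste(need, collapse = ", ")))
  }
  if (any(segments$end <= segments$start)) abort("segment end must exceed start")
  if (any(segments$probe_count < 1)) abort("probe_count must be >= 1")
  known <- segments$type %in% c("gain", "loss", "cnLOH")
  if (any(!known)) {
    inform(paste0(sum(!known), " segment(s) with unknown type dropped"))
  }
  seg <- segments[known, , drop = FALSE]
  keep <- (seg$type == "loss" & seg$probe_count >= probes_loss) |
    (seg$type == "gain" & seg$probe_count >= probes_gain) |
    (seg$type == "cnLOH" & (seg$end - seg$start) >= cnloh_mb * 1e6)
  out <- seg[keep, , drop = FALSE]
  counts <- dplyr::full_join(
    dplyr::count(seg, .data$type, name = "n_input"),
    dplyr::count(out, .data$type, name = "n_retained"),
    by = "type"
  ) |>
    dplyr::mutate(n_retained = dplyr::coalesce(.data$n_retained, 0L))
  attr(out, "counts") <- counts
  out
}

#' Convert 1-based inclusive intervals to 0-based half-open
#'
#' @param tbl Tibble with `start`, `end` columns in 1-based inclusive
#'   coordinates.
#' @return The tibble with `start` decremented (end is unchanged: a
#'   1-based inclusive end equals the 0-based half-open end).
#' @export
to_zero_based <- function(tbl) {
  stopifnot(all(c("start", "end") %in% names(tbl)))
  dplyr::mutate(tbl, start = .data$start - 1)
}

#' Gene-level copy-number calls and alteration frequencies
#'
#' Assigns each gene, in each sample, the type of the retained segment
#' with maximal overlap (no overlapping segment means neutral; two
#' contradictory segments with exactly equal overlap yield neutral with an
#' ambiguity flag), then tabulates per-gene alteration frequencies across
#' the cohort.
#'
#' @param retained Filtered segment tibble (see [filter_cn_segments()])
#'   with a `sample` column.
#' @param gene_coords Tibble `gene`, `chromosome`, `start`, `end` on the
#'   same 0-based half-open convention as the segments (use
#'   [to_zero_based()] for 1-based input).
#' @param samples Cohort sample labels (calls are emitted for every
#'   sample, including those without segments).
#' @return A list: `calls` (tibble `gene`, `sample`, `state`, `flag`) and
#'   `frequency` (tibble `gene`, `type`, `n_altered`, `frequency`).
#' @export
gene_level_cn_summary <- function(retained, gene_coords, samples) {
  stopifnot(is.data.frame(retained), is.data.frame(gene_coords))
  if (!"sample" %in% names(retained)) {
    abort("retained segments must carry a `sample` column")
  }
  samples <- unique(as.character(samples))
  overlaps <- dplyr::inner_join(
    gene_coords |>
      dplyr::rename(g_start = "start", g_end = "end"),
    retained |>
      dplyr::rename(s_start = "start", s_end = "end"),
    by = "chromosome", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      overlap = pmin(.data$g_end, .data$s_end) - pmax(.data$g_start, .data$s_start)
    ) |>
    dplyr::filter(.data$overlap > 0)
  best <- overlaps |>
    dplyr::group_by(.data$gene, .data$sample) |>
    dplyr::summarise(
      state = {
        mx <- .data$type[.data$overlap == max(.data$overlap)]
        if (length(unique(mx)) > 1) "neutral" else mx[1]
      },
      flag = {
        mx <- .data$type[.data$overlap == max(.data$overlap)]
        if (length(unique(mx)) > 1) "ambiguous" else NA_character_
      },
      .groups = "drop"
    )
  calls <- tidyr::crossing(gene = gene_coords$gene, sample = samples) |>
    dplyr::left_join(best, by = c("gene", "sample")) |>
    dplyr::mutate(state = dplyr::coalesce(.data$state, "neutral"))
  frequency <- calls |>
    dplyr::filter(.data$state != "neutral") |>
    dplyr::count(.data$gene, type = .data$state, name = "n_altered") |>
    dplyr::mutate(frequency = .data$n_altered / length(samples))
  list(calls = calls, frequency = frequency)
}

#' Discretize copy-number values into GISTIC-style categories
#'
#' Maps continuous gene-level copy number on the log2(relative to
#' ploidy + 1) scale (neutral encodes to exactly 1) to the five-level
#' scheme: -2 homozygous deletion, -1 hemizygous deletion, 0 neutral,
#' 1 gain, 2 high-level amplification.  The mapping is monotone
#' non-decreasing; the default cut points put zero copies (value 0) at -2
#' and at-ploidy (value 1) at 0.  Cut points are configurable because
#' sample-adaptive thresholding is not reproducible locally.
#'
#' @param cn_value Numeric vector; `NA`/`NaN` is rejected.
#' @param cuts Four increasing thresholds `(homdel, hetloss, gain, amp)`:
#'   values below `cuts[1]` map to -2, below `cuts[2]` to -1, up to
#'   `cuts[3]` (inclusive) to 0, up to `cuts[4]` (inclusive) to 1, above
#'   to 2.
#' @return Integer vector of categories in `{-2, -1, 0, 1, 2}`.
#' @export
gistic_categorize <- function(cn_value, cuts = c(0.3, 0.8, 1.2, 1.55)) {
  if (any(!is.finite(cn_value))) abort("copy-number values must be finite")
  if (length(cuts) != 4 || any(diff(cuts) <= 0)) {
    abort("`cuts` must be 4 increasing thresholds")
  }
  out <- integer(length(cn_value))
  out[cn_value < cuts[1]] <- -2L
  out[cn_value >= cuts[1] & cn_value < cuts[2]] <- -1L
  out[cn_value >= cuts[2] & cn_value <= cuts[3]] <- 0L
  out[cn_value > cuts[3] & cn_value <= cuts[4]] <- 1L
  out[cn_value > cuts[4]] <- 2L
  out
}
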