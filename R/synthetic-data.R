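#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generators: cohort size and
#' planted differential expression, the variance prior from which gene-wise
#' variances are drawn, the perturbation-library composition (how many drugs,
#' how many true reversers, how strongly they reverse), the viability screen
#' (dose ladder, number of screened lines, the planted biomarker and its
#' copy-number/sensitivity correlation) and the copy-number segment cohort.
#' Defaults define the package's reference study conditions: a 5000-gene
#' cohort of 30 tumors vs 30 normals with 10% differentially expressed genes
#' at |log2FC| = 2, a 200-drug library with 20 reversers of strength 0.8
#' profiled in 4 cell lines, an 8-point 4-fold dose ladder from 10 uM down
#' to ~600 pM, a 30-line viability screen with a planted copy-number
#' biomarker at r = -0.8, and a 32-sample segment cohort with 8 planted
#' biomarker gains.
#'
#' @param n_genes,n_tumor,n_normal Cohort dimensions.
#' @param frac_de Fraction of genes differentially expressed (0 allowed for
#'   a pure null cohort; if positive, `frac_de * n_genes` must be >= 10).
#' @param lfc_mean Magnitude of the planted log2 fold change (sign is drawn
#'   at random per gene).
#' @param d0,s0_sq Variance prior: gene variances are drawn from a scaled
#'   inverse-chi-square with `d0` prior degrees of freedom and prior
#'   variance `s0_sq` (log2 scale).
#' @param n_drugs,n_reversers Library composition; `n_reversers <= n_drugs`.
#' @param reversal_strength In `[0, 1]`; scales how strongly a reverser's
#'   profile opposes the planted fold changes.
#' @param cell_lines Labels of the perturbation-library cell lines.
#' @param dose_ladder Strictly decreasing positive doses in uM; default the
#'   8-point 4-fold ladder from 10 uM.
#' @param dispersion Negative-binomial dispersion used in counts mode.
#' @param profile_genes Size of the perturbation-profile gene universe
#'   (default 978, the landmark-gene convention); capped at `n_genes`.
#' @param profile_noise_sd Gaussian noise sd of profile differential values.
#' @param n_screen_lines Number of cell lines in the viability screen.
#' @param n_tumorlike_lines Screen lines whose expression is planted to
#'   resemble the tumor signature (the lines the model-matching stage
#'   should find).
#' @param n_biomarker_drugs How many screened drugs carry the planted
#'   biomarker link (first drugs of the reverser set).
#' @param planted_cn_sensitivity_r Planted Pearson correlation between
#'   biomarker copy number and drug sensitivity, in `[-1, 0]`.
#' @param biomarker_gene,null_biomarker_gene Labels for the linked and the
#'   unlinked control biomarker (defaults `"TOP2A"`/`"TOP2B"`).
#' @param n_segments Number of copy-number segments to emit (including the
#'   fixed boundary fixtures).
#' @param n_cn_samples Size of the segment cohort.
#' @param n_biomarker_gains How many cohort samples carry a retained gain
#'   over the biomarker locus.
#' @param seed Master seed; all generators derive stage seeds from it.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_expression_cohort()], [generate_perturbation_library()],
#'   [generate_viability_screen()], [generate_cn_segments()],
#'   [generate_geneset_library()]
#' @export
sim_config <- function(n_genes = 5000, n_tumor = 30, n_normal = 30,
                       frac_de = 0.1, lfc_mean = 2,
                       d0 = 4, s0_sq = 0.05,
                       n_drugs = 200, n_reversers = 20,
                       reversal_strength = 0.8,
                       cell_lines = paste0("CL", 1:4),
                       dose_ladder = 10 / 4^(0:7),
                       dispersion = 0.1,
                       profile_genes = 978,
                       profile_noise_sd = 1,
                       n_screen_lines = 30,
                       n_tumorlike_lines = 5,
                       n_biomarker_drugs = 6,
                       planted_cn_sensitivity_r = -0.8,
                       biomarker_gene = "TOP2A",
                       null_biomarker_gene = "TOP2B",
                       n_segments = 40,
                       n_cn_samples = 32,
                       n_biomarker_gains = 8,
                       seed = 0L) {
  num_fields <- list(
    n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
    frac_de = frac_de, lfc_mean = lfc_mean, d0 = d0, s0_sq = s0_sq,
    n_drugs = n_drugs, n_reversers = n_reversers,
    reversal_strength = reversal_strength, dispersion = dispersion,
    profile_genes = profile_genes, profile_noise_sd = profile_noise_sd,
    n_screen_lines = n_screen_lines, n_tumorlike_lines = n_tumorlike_lines,
    n_biomarker_drugs = n_biomarker_drugs,
    planted_cn_sensitivity_r = planted_cn_sensitivity_r,
    n_segments = n_segments, n_cn_samples = n_cn_samples,
    n_biomarker_gains = n_biomarker_gains, seed = seed
  )
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (length(v) != 1 || !is.numeric(v) || !is.finite(v)) {
      abort(paste0("configuration field `", nm, "` must be a single finite number"))
    }
  }
  if (any(!is.finite(dose_ladder))) abort("configuration field `dose_ladder` must be finite")
  n_genes <- check_count(n_genes, "n_genes")
  n_tumor <- check_count(n_tumor, "n_tumor", min = 2)
  n_normal <- check_count(n_normal, "n_normal", min = 2)
  frac_de <- check_fraction(frac_de, "frac_de")
  if (frac_de > 0 && frac_de * n_genes < 10) {
    abort("`frac_de * n_genes` must be at least 10 when frac_de > 0")
  }
  d0 <- check_positive(d0, "d0")
  s0_sq <- check_positive(s0_sq, "s0_sq")
  n_drugs <- check_count(n_drugs, "n_drugs")
  n_reversers <- check_count(n_reversers, "n_reversers", min = 0)
  if (n_reversers > n_drugs) abort("`n_reversers` cannot exceed `n_drugs`")
  reversal_strength <- check_fraction(reversal_strength, "reversal_strength",
                                      open_hi = FALSE)
  if (length(cell_lines) < 1 || anyDuplicated(cell_lines)) {
    abort("`cell_lines` must be a non-empty list of unique labels")
  }
  if (length(dose_ladder) < 1 || any(dose_ladder <= 0) ||
      any(diff(dose_ladder) >= 0)) {
    abort("`dose_ladder` must be strictly decreasing and positive")
  }
  if (planted_cn_sensitivity_r < -1 || planted_cn_sensitivity_r > 0) {
    abort("`planted_cn_sensitivity_r` must lie in [-1, 0]")
  }
  cfg <- list(
    n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
    frac_de = frac_de, lfc_mean = as.numeric(lfc_mean),
    d0 = d0, s0_sq = s0_sq,
    n_drugs = n_drugs, n_reversers = n_reversers,
    reversal_strength = reversal_strength,
    cell_lines = as.character(cell_lines),
    dose_ladder = as.numeric(dose_ladder),
    dispersion = check_positive(dispersion, "dispersion"),
    profile_genes = min(check_count(profile_genes, "profile_genes"), n_genes),
    profile_noise_sd = check_positive(profile_noise_sd, "profile_noise_sd"),
    n_screen_lines = check_count(n_screen_lines, "n_screen_lines", min = 3),
    n_tumorlike_lines = check_count(n_tumorlike_lines, "n_tumorlike_lines", min = 0),
    n_biomarker_drugs = check_count(n_biomarker_drugs, "n_biomarker_drugs", min = 1),
    planted_cn_sensitivity_r = as.numeric(planted_cn_sensitivity_r),
    biomarker_gene = as.character(biomarker_gene),
    null_biomarker_gene = as.character(null_biomarker_gene),
    n_segments = check_count(n_segments, "n_segments", min = 6),
    n_cn_samples = check_count(n_cn_samples, "n_cn_samples", min = 1),
    n_biomarker_gains = check_count(n_biomarker_gains, "n_biomarker_gains", min = 0),
    seed = as.integer(seed)
  )
  if (cfg$n_tumorlike_lines > cfg$n_screen_lines) {
    abort("`n_tumorlike_lines` cannot exceed `n_screen_lines`")
  }
  if (cfg$n_biomarker_gains > cfg$n_cn_samples) {
    abort("`n_biomarker_gains` cannot exceed `n_cn_samples`")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes, ", x$n_tumor, "T/", x$n_normal,
      "N, frac_de = ", x$frac_de, ", ", x$n_drugs, " drugs (",
      x$n_reversers, " reversers @ strength ", x$reversal_strength,
      "), seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Planted truth: which genes are differential (and by how much), which drugs
# reverse, which gene is the sensitivity biomarker.  Downstream analysis
# operations never read this object; only tests and the acceptance script do.
new_ground_truth <- function(de_genes, reverser_drugs, biomarker_gene,
                             planted_cn_sensitivity_r, tumorlike_lines = character()) {
  structure(
    list(de_genes = de_genes, reverser_drugs = reverser_drugs,
         biomarker_gene = biomarker_gene,
         planted_cn_sensitivity_r = planted_cn_sensitivity_r,
         tumorlike_lines = tumorlike_lines),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$de_genes), " planted DE genes, ",
      length(x$reverser_drugs), " reverser drugs, biomarker ",
      x$biomarker_gene, " (planted r = ", x$planted_cn_sensitivity_r,
      ")\n", sep = "")
  invisible(x)
}

# Deterministic planted-effect channel: which genes are DE and their signed
# log2FC, derived from the master seed only (not the noise seed), so cohorts
# regenerated with different noise share the same planted core.
planted_de <- function(config) {
  set.seed(split_seed(config$seed, "cohort"))
  genes <- gene_labels(config$n_genes)
  n_de <- round(config$frac_de * config$n_genes)
  if (n_de == 0) return(setNames(numeric(0), character(0)))
  idx <- sample.int(config$n_genes, n_de)
  lfc <- sample(c(-1, 1), n_de, replace = TRUE) * config$lfc_mean
  setNames(lfc, genes[idx])
}

#' Simulate a tumor-vs-normal expression cohort with planted effects
#'
#' Normal samples are Gaussian per gene around a gene-specific baseline with
#' gene variance drawn from a scaled inverse-chi-square(d0, s0_sq) prior
#' (the same hierarchical model the moderated t-test assumes); tumor samples
#' are shifted by the planted signed log2 fold change for the differential
#' genes.  In counts mode the same fold changes act multiplicatively on
#' negative-binomial means with gene-wise dispersion `config$dispersion`.
#'
#' @param config A [sim_config()].
#' @param scale `"log_intensity"` (default) or `"counts"`.
#' @param noise_seed Optional seed for the sampling noise only; the planted
#'   DE gene set depends solely on `config$seed`, so varying `noise_seed`
#'   yields independent cohorts sharing the same planted core.
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (the planted-effect record).
#' @examples
#' cohort <- generate_expression_cohort(sim_config(n_genes = 200, seed = 1))
#' cohort$matrix
#' @export
generate_expression_cohort <- function(config,
                                       scale = c("log_intensity", "counts"),
                                       noise_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  scale <- match.arg(scale)
  lfc <- planted_de(config)
  genes <- gene_labels(config$n_genes)
  lfc_vec <- setNames(numeric(config$n_genes), genes)
  lfc_vec[names(lfc)] <- lfc

  set.seed(noise_seed %||% split_seed(config$seed, "cohort_noise"))
  n_s <- config$n_tumor + config$n_normal
  baseline <- rnorm(config$n_genes, mean = 7, sd = 1)
  gene_var <- config$s0_sq * config$d0 / rchisq(config$n_genes, df = config$d0)

  samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
               sprintf("N%03d", seq_len(config$n_normal)))
  groups <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))

  if (scale == "log_intensity") {
    mu <- outer(baseline, rep(1, n_s)) +
      outer(lfc_vec, as.numeric(groups == "tumor"))
    vals <- mu + sqrt(gene_var) * matrix(rnorm(config$n_genes * n_s),
                                         config$n_genes, n_s)
  } else {
    mu_norm <- 2^baseline
    mu <- outer(mu_norm, rep(1, n_s)) *
      2^outer(lfc_vec, as.numeric(groups == "tumor"))
    vals <- matrix(
      rnbinom(config$n_genes * n_s, mu = as.vector(mu),
              size = 1 / config$dispersion),
      config$n_genes, n_s
    )
  }
  dimnames(vals) <- list(genes, samples)
  truth <- new_ground_truth(
    de_genes = lfc,
    reverser_drugs = head(drug_labels(config$n_drugs), config$n_reversers),
    biomarker_gene = config$biomarker_gene,
    planted_cn_sensitivity_r = config$planted_cn_sensitivity_r,
    tumorlike_lines = sprintf("SCL%02d", seq_len(config$n_tumorlike_lines))
  )
  list(matrix = expression_matrix(vals, scale = scale, groups = groups),
       truth = truth)
}

# Saturating potency of a dose in uM; near-maximal at the 10 uM reference.
default_potency <- function(dose) dose / (dose + 1)

#' Simulate a drug perturbation-profile library
#'
#' Emulates an L1000-style library of differential-expression profiles, one
#' per drug x cell line x dose x time.  Every drug is profiled in each
#' configured cell line at the 10 uM / 24 h reference condition, plus one
#' low-dose (2.5 uM) and one short-time (6 h) profile in the first cell
#' line, so each drug has at least three profiles and the dose/time
#' adjustment of [estimate_dose_time_offsets()] is exercised.  Reverser
#' drugs oppose the planted fold changes scaled by `reversal_strength` and
#' a saturating potency of dose; all other drugs are pure noise.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_expression_cohort()].
#' @param potency_fun Saturating increasing function of dose in uM; the
#'   default `dose/(dose + 1)` is near-maximal at 10 uM.  Pass
#'   `function(d) 1` for a dose-flat library.
#' @return A tibble with columns `drug`, `cell_line`, `dose_uM`, `time_h`,
#'   `gene`, `value` (one row per gene per profile).
#' @export
generate_perturbation_library <- function(config, truth,
                                          potency_fun = default_potency) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$cell_lines) == 0) abort("empty cell-line list")
  if (config$n_reversers > 0 && length(truth$de_genes) == 0) {
    abort("cannot plant reversers against an empty DE gene set")
  }
  universe <- head(gene_labels(config$n_genes), config$profile_genes)
  n_u <- length(universe)
  drugs <- drug_labels(config$n_drugs)
  reversers <- truth$reverser_drugs

  conditions <- dplyr::bind_rows(
    tibble::tibble(cell_line = config$cell_lines, dose_uM = 10, time_h = 24),
    tibble::tibble(cell_line = config$cell_lines[1], dose_uM = 2.5, time_h = 24),
    tibble::tibble(cell_line = config$cell_lines[1], dose_uM = 10, time_h = 6)
  )
  grid <- tidyr::crossing(drug = drugs, conditions)

  # Signed reversal template over the profile universe (0 off the signature).
  template <- setNames(numeric(n_u), universe)
  planted <- intersect(names(truth$de_genes), universe)
  template[planted] <- truth$de_genes[planted]

  set.seed(split_seed(config$seed, "library"))
  n_prof <- nrow(grid)
  noise <- matrix(rnorm(n_prof * n_u, sd = config$profile_noise_sd), n_u, n_prof)
  signal <- outer(
    -config$reversal_strength * template,
    ifelse(grid$drug %in% reversers, vapply(grid$dose_uM, potency_fun, 0), 0)
  )
  vals <- signal + noise
  tibble::tibble(
    drug = rep(grid$drug, each = n_u),
    cell_line = rep(grid$cell_line, each = n_u),
    dose_uM = rep(grid$dose_uM, each = n_u),
    time_h = rep(grid$time_h, each = n_u),
    gene = rep(universe, times = n_prof),
    value = as.vector(vals)
  )
}

#' Simulate a dose-response viability screen with a planted biomarker link
#'
#' Per drug x cell line, viability log2 fold change follows a saturating
#' Hill-type decreasing curve over the configured dose ladder.  For the
#' biomarker-linked drugs (the first `n_biomarker_drugs` reversers) the
#' curve amplitude is constructed from the line's standardized biomarker
#' copy number so that the Pearson correlation between copy number and the
#' AUC sensitivity metric equals `planted_cn_sensitivity_r` in expectation;
#' remaining drugs get amplitudes with no biomarker signal.  Matched
#' gene-level copy-number [log2(relative to ploidy + 1)] and expression
#' [log2(TPM+1)] tables are emitted for the screened lines, including a
#' planted tumor-like expression pattern in the first
#' `n_tumorlike_lines` lines (for the model-matching stage) and an
#' uncorrelated control biomarker.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_expression_cohort()].
#' @param n_lines Number of screened lines (default `config$n_screen_lines`).
#' @return A list of tibbles: `curves` (`drug`, `cell_line`, `dose_uM`,
#'   `viability_log2fc`), `cn` (`gene`, `cell_line`, `cn`), `expression`
#'   (`gene`, `cell_line`, `expression`).
#' @export
generate_viability_screen <- function(config, truth,
                                      n_lines = config$n_screen_lines) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$dose_ladder) < 2) abort("dose ladder needs at least 2 points")
  r <- config$planted_cn_sensitivity_r
  if (r < -1 || r > 0) abort("planted correlation must lie in [-1, 0]")
  n_lines <- check_count(n_lines, "n_lines", min = 3)
  lines <- sprintf("SCL%02d", seq_len(n_lines))
  drugs <- truth$reverser_drugs
  if (length(drugs) == 0) abort("no screened drugs: truth has no reversers")
  bm_drugs <- head(drugs, config$n_biomarker_drugs)

  set.seed(split_seed(config$seed, "viability"))
  z_cn <- rnorm(n_lines)
  cn_bm <- 1 + 0.15 * z_cn            # log2(rel ploidy + 1); neutral = 1

  doses <- config$dose_ladder
  # normalized trapezoid weights of the AUC metric over log10 dose, so the
  # planted amplitude is linear in the measured AUC and the CN link carries
  # through the Hill curve exactly
  x <- log10(sort(doses))
  w_asc <- (c(diff(x) / 2, 0) + c(0, diff(x) / 2)) / (max(x) - min(x))
  w <- w_asc[match(log10(doses), x)]

  a0 <- 2; a_sd <- 0.6
  depth <- function(linked) {
    # target weighted-average viability depth per line (equals -AUC)
    eps <- rnorm(n_lines)
    if (linked) a0 + a_sd * (abs(r) * z_cn + sqrt(1 - r^2) * eps)
    else a0 + a_sd * eps
  }
  curves <- purrr::map_dfr(drugs, function(d) {
    target <- depth(d %in% bm_drugs)
    ic50 <- 0.5 * exp(rnorm(n_lines, sd = 0.1))
    hill <- outer(1 / ic50, doses, function(inv, dd) dd * inv / (dd * inv + 1))
    hbar <- as.vector(hill %*% w)    # weighted mean inhibition per line
    a <- target / hbar
    v <- -a * hill + matrix(rnorm(n_lines * length(doses), sd = 0.02),
                            n_lines, length(doses))
    tibble::tibble(
      drug = d,
      cell_line = rep(lines, times = length(doses)),
      dose_uM = rep(doses, each = n_lines),
      viability_log2fc = as.vector(v)
    )
  })

  # Gene-level CN: planted biomarker, flat control biomarker, filler genes.
  filler <- head(setdiff(gene_labels(config$n_genes),
                         c(config$biomarker_gene, config$null_biomarker_gene)), 48)
  cn_genes <- c(config$biomarker_gene, config$null_biomarker_gene, filler)
  cn_vals <- rbind(cn_bm, 1 + 0.15 * rnorm(n_lines),
                   matrix(1 + 0.1 * rnorm(length(filler) * n_lines),
                          length(filler), n_lines))
  cn <- tibble::tibble(
    gene = rep(cn_genes, times = n_lines),
    cell_line = rep(lines, each = length(cn_genes)),
    cn = as.vector(cn_vals)
  )

  # Expression: biomarker tracks its copy number; a slice of the planted DE
  # genes carries the tumor-like pattern in the designated lines.
  de <- truth$de_genes
  sig_genes <- head(names(de), 300)
  extra <- head(setdiff(gene_labels(config$n_genes),
                        c(sig_genes, cn_genes)), 100)
  expr_genes <- unique(c(config$biomarker_gene, config$null_biomarker_gene,
                         sig_genes, extra))
  base <- matrix(5 + rnorm(length(expr_genes) * n_lines, sd = 0.5),
                 length(expr_genes), n_lines,
                 dimnames = list(expr_genes, lines))
  base[config$biomarker_gene, ] <- 5 + 0.8 * z_cn + 0.3 * rnorm(n_lines)
  tumorlike <- head(lines, config$n_tumorlike_lines)
  if (length(sig_genes) && length(tumorlike)) {
    base[sig_genes, tumorlike] <- base[sig_genes, tumorlike] +
      matrix(rep(0.75 * de[sig_genes], length(tumorlike)),
             length(sig_genes), length(tumorlike))
  }
  base[base < 0] <- 0
  expression <- tibble::tibble(
    gene = rep(expr_genes, times = n_lines),
    cell_line = rep(lines, each = length(expr_genes)),
    expression = as.vector(base)
  )
  list(curves = curves, cn = cn, expression = expression)
}

#' Coordinates of the synthetic genes placed on the segment assembly
#'
#' 0-based half-open intervals on the synthetic assembly used by
#' [generate_cn_segments()]; includes the biomarker locus plus a few
#' unaltered control genes.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene`, `chromosome`, `start`, `end`.
#' @export
synthetic_gene_coords <- function(config) {
  tibble::tibble(
    gene = c(config$biomarker_gene, config$null_biomarker_gene,
             "CTRL1", "CTRL2"),
    chromosome = c("chr17", "chr3", "chr1", "chr9"),
    start = c(39650000L, 25639000L, 12000000L, 5000000L),
    end = c(39680000L, 25770000L, 12050000L, 5040000L)
  )
}

#' Simulate a copy-number segment cohort
#'
#' Emits per-sample segments (0-based half-open, with probe counts and a
#' type among gain / loss / cnLOH) that deliberately straddle the retention
#' thresholds of [filter_cn_segments()] on both sides: every cohort contains
#' a loss with 24 and one with 25 probes, a gain with 49 and one with 50
#' probes, and a cnLOH of 4,999,999 and one of 5,000,000 bp.  A configurable
#' number of samples carry a retained gain over the biomarker locus so the
#' gene-level alteration frequency is known by construction.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `sample`, `chromosome`, `start`, `end`,
#'   `probe_count`, `type`.
#' @export
generate_cn_segments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sprintf("P%03d", seq_len(config$n_cn_samples))
  fixtures <- tibble::tibble(
    sample = samples[1],
    chromosome = "chr2",
    start = c(1e6, 3e6, 5e6, 7e6, 9e6, 16e6),
    end = c(1e6 + 2e5, 3e6 + 2e5, 5e6 + 4e5, 7e6 + 4e5,
            9e6 + 4999999, 16e6 + 5000000),
    probe_count = c(24L, 25L, 49L, 50L, 1000L, 1000L),
    type = c("loss", "loss", "gain", "gain", "cnLOH", "cnLOH")
  )
  coords <- synthetic_gene_coords(config)
  bm <- coords[coords$gene == config$biomarker_gene, ]
  gains <- tibble::tibble(
    sample = head(samples, config$n_biomarker_gains),
    chromosome = bm$chromosome,
    start = bm$start - 500000,
    end = bm$end + 500000,
    probe_count = 200L,
    type = "gain"
  )
  n_rand <- config$n_segments - nrow(fixtures) - nrow(gains)
  if (n_rand < 0) abort("`n_segments` too small for the fixed fixtures")
  set.seed(split_seed(config$seed, "segments"))
  rand <- tibble::tibble(
    sample = sample(samples, n_rand, replace = TRUE),
    chromosome = sample(paste0("chr", c(4:8, 10:12)), n_rand, replace = TRUE),
    start = as.numeric(sample.int(8e7, n_rand)),
    end = NA_real_,
    probe_count = sample(c(5:80, 100:400), n_rand, replace = TRUE),
    type = sample(c("gain", "loss", "cnLOH"), n_rand, replace = TRUE)
  )
  rand$end <- rand$start +
    ifelse(rand$type == "cnLOH",
           runif(n_rand, 1e6, 9e6),
           runif(n_rand, 1e5, 2e6))
  rand$end <- round(rand$end)
  out <- dplyr::bind_rows(fixtures, gains, rand)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  out
}

#' Simulate a gene-set library with one planted true pathway
#'
#' Builds a GMT-style library whose first set (`"PLANTED_PATHWAY"`) is a
#' subset of the planted differential genes while every decoy set is drawn
#' uniformly from the gene universe, so over-representation of the true
#' pathway (and only it) is guaranteed by construction.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_expression_cohort()].
#' @param n_sets Total number of sets including the planted one.
#' @param set_size Genes per set; must not exceed the universe size.
#' @return A `geneset_library` (see [geneset_library()]).
#' @export
generate_geneset_library <- function(config, truth, n_sets = 50,
                                     set_size = 25) {
  stopifnot(inherits(config, "sim_config"))
  universe <- gene_labels(config$n_genes)
  set_size <- check_count(set_size, "set_size")
  if (set_size > length(universe)) {
    abort("`set_size` exceeds the gene universe")
  }
  if (length(truth$de_genes) == 0) abort("truth has no planted DE genes")
  set.seed(split_seed(config$seed, "genesets"))
  true_set <- sample(names(truth$de_genes),
                     min(set_size, length(truth$de_genes)))
  decoys <- lapply(seq_len(n_sets - 1), function(i) sample(universe, set_size))
  names(decoys) <- sprintf("DECOY_%03d", seq_len(n_sets - 1))
  geneset_library(
    name = "synthetic",
    sets = c(list(PLANTED_PATHWAY = true_set), decoys),
    universe = universe
  )
}
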