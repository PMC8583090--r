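# Internal helpers shared across modules.

# Derive a stage-specific RNG seed from the master seed so stages can be
# regenerated independently.  Kept below 2^31 - 1.
split_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 101L, cohort_noise = 211L, library = 307L, viability = 401L,
    segments = 503L, genesets = 601L, null_ranks = 701L, dependency = 809L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown seed stage '", stage, "'"))
  }
  (abs(as.integer(seed)) %% 9000001L) * 211L + offsets[[stage]]
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min,
                 " (got ", deparse(substitute(x)), " = ", format(x), ")"))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = TRUE) {
  if (length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  if (x < lo || x > hi || (open_hi && x >= hi)) {
    abort(paste0("`", name, "` = ", format(x), " is outside its valid range"))
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive finite number"))
  }
  as.numeric(x)
}

gene_labels <- function(n) sprintf("g%05d", seq_len(n))
drug_labels <- function(n) sprintf("drug%03d", seq_len(n))
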