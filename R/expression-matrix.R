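#' Construct an expression matrix with scale and group metadata
#'
#' The container used by the signature-building stage: a genes-by-samples
#' numeric matrix together with the scale its values are on and a
#' tumor/normal group label per sample.  Values may be log-intensities
#' (microarray), raw counts (RNA-seq) or log2(TPM+1); the scale is declared
#' explicitly rather than guessed, and the differential-expression stage
#' refuses scales it cannot handle.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   dimnames set.  Duplicate gene labels (e.g. multiple probes per symbol)
#'   are allowed here and collapsed later by [build_signature()].
#' @param scale One of `"log_intensity"`, `"counts"`, `"log2_tpm1"`.
#' @param groups Character vector (or named vector keyed by sample) of
#'   `"tumor"`/`"normal"` labels, one per column.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expression_matrix(
#'   matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4))),
#'   scale = "log_intensity", groups = c("tumor", "tumor", "normal", "normal")
#' )
#' m
#' @export
expression_matrix <- function(values,
                              scale = c("log_intensity", "counts", "log2_tpm1"),
                              groups) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(colnames(values))) abort("duplicate sample labels")
  if (!is.null(names(groups))) groups <- groups[colnames(values)]
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    abort("`groups` must supply one label per sample")
  }
  if (!all(groups %in% c("tumor", "normal"))) {
    abort("group labels must be 'tumor' or 'normal'")
  }
  if (!all(c("tumor", "normal") %in% groups)) {
    abort("both tumor and normal groups must be non-empty")
  }
  if (scale == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      abort("counts mode requires non-negative integer values")
    }
  }
  structure(
    list(values = values, scale = scale,
         groups = setNames(groups, colnames(values))),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$groups == "tumor"), " tumor / ",
      sum(x$groups == "normal"), " normal), scale = ", x$scale, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Long-format view of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `group`, `value`.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    group = rep(unname(x$groups), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
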