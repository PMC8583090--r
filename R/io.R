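#' Write / read an expression matrix as TSV
#'
#' The on-disk dialect is a plain genes-x-samples TSV preceded by a
#' one-line scale header (`#scale=log_intensity|counts|log2_tpm1`), with
#' the tumor/normal group labels in a sidecar sample-annotation table
#' (`<path>.samples.tsv`: columns `sample`, `group`).  The round trip is
#' lossless for values, labels, groups and scale.
#'
#' @param m An [expression_matrix()].
#' @param path Output TSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  writeLines(paste0("#scale=", m$scale), path)
  tbl <- tibble::as_tibble(as.data.frame(m$values), rownames = "gene")
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  readr::write_tsv(
    tibble::tibble(sample = names(m$groups), group = unname(m$groups)),
    paste0(path, ".samples.tsv")
  )
  invisible(path)
}

#' @rdname write_expression
#' @param samples_path Sidecar annotation path (default `<path>.samples.tsv`).
#' @export
read_expression <- function(path, samples_path = paste0(path, ".samples.tsv")) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#scale=")) {
    abort("expression file must start with a '#scale=' header line")
  }
  scale <- sub("^#scale=", "", header)
  tbl <- readr::read_tsv(path, skip = 1, show_col_types = FALSE,
                         progress = FALSE, name_repair = "minimal")
  if (anyDuplicated(names(tbl)[-1])) abort("duplicate sample labels")
  mat_cols <- tbl[, -1, drop = FALSE]
  for (jc in seq_along(mat_cols)) {
    col <- mat_cols[[jc]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      abort(paste0("non-numeric cell at row ", bad, ", column '",
                   names(mat_cols)[jc], "'"))
    }
  }
  vals <- as.matrix(mat_cols)
  rownames(vals) <- as.character(tbl[[1]])
  if (scale == "counts" && any(vals != round(vals))) {
    idx <- which(vals != round(vals), arr.ind = TRUE)[1, ]
    abort(paste0("counts file contains a non-integer value at row ", idx[1],
                 " ('", rownames(vals)[idx[1]], "'), column '",
                 colnames(vals)[idx[2]], "'"))
  }
  ann <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  groups <- setNames(ann$group, ann$sample)
  expression_matrix(vals, scale = scale, groups = groups)
}

#' Write / read gene-set libraries in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.  Duplicate members within a set are collapsed with a
#' warning on read; lines with fewer than 3 fields or empty sets are
#' errors (reported with their line number).  The library universe is not
#' part of the GMT format and must be supplied explicitly on read.
#'
#' @param library A [geneset_library()].
#' @param path GMT file path.
#' @param descriptions Optional named character of per-set descriptions.
#' @return `path` invisibly (write); a [geneset_library()] (read).
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  stopifnot(inherits(library, "geneset_library"))
  lines <- vapply(names(library$sets), function(nm) {
    desc <- descriptions[[nm]] %||% "na"
    paste(c(nm, desc, library$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param name Library label for the read result.
#' @param universe Background gene universe; defaults to the union of all
#'   set members.
#' @export
read_gmt <- function(path, name = basename(path), universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      abort(paste0("GMT line ", i, " has fewer than 3 tab-separated fields"))
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) abort(paste0("GMT line ", i, " defines an empty set"))
    if (anyDuplicated(members)) {
      warn(paste0("GMT line ", i, " ('", f[1], "'): ",
                  sum(duplicated(members)), " duplicate member(s) collapsed"))
      members <- unique(members)
    }
    sets[[f[1]]] <- members
  }
  geneset_library(name, sets,
                  universe %||% unique(unlist(sets, use.names = FALSE)))
}
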