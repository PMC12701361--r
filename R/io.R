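# File formats: GMT gene sets and the TSV tables exchanged between pipeline
# stages. TSV with header is the universal tabular dialect; everything is
# line-oriented and diff-able.

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line as
#' `term<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated with a warning; duplicate term names or lines with
#' fewer than three fields are errors reported with their line number.
#'
#' @param path File path.
#' @return Named list of character vectors with a `descriptions` attribute
#'   (named character vector). Empty files give an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) stopf("GMT line %d has fewer than 3 fields", short[1])
  terms <- vapply(fields, `[[`, character(1), 1)
  dup <- which(duplicated(terms))
  if (length(dup)) stopf("duplicate term name '%s' at GMT line %d", terms[dup[1]], dup[1])
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    if (anyDuplicated(genes)) {
      warnf("duplicate gene(s) within term '%s'; deduplicated", terms[i])
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- terms
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, character(1), 2), terms)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector; defaults to the
#'   collection's `descriptions` attribute or `"na"`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(collection, "descriptions") %||%
    setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(tm) {
    paste(c(tm, descriptions[[tm]] %||% "na", collection[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Quiet TSV round trip helpers.
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read an abundance matrix and sample metadata
#'
#' @param matrix_path TSV whose first column (`protein`) holds protein
#'   labels and remaining columns one sample each (log2 intensities).
#' @param meta_path TSV with columns `sample`, `cell_line`, `sirna`,
#'   `replicate`.
#' @return List with `values` (matrix) and `meta` (tibble).
#' @export
read_abundance <- function(matrix_path, meta_path) {
  tbl <- read_tsv_quiet(matrix_path)
  values <- as.matrix(tbl[, -1])
  rownames(values) <- tbl[[1]]
  meta <- read_tsv_quiet(meta_path)
  if (!all(meta$sample %in% colnames(values))) {
    stopf("sample metadata names samples absent from the abundance matrix")
  }
  list(values = values[, meta$sample, drop = FALSE], meta = meta)
}
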