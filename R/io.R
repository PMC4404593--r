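#' Read and write tab-delimited expression matrices
#'
#' The on-disk dialect is a plain tab-delimited table: a header row of sample
#' identifiers, one row per probe, first column `probe_id`. Values are log2
#' intensities.
#'
#' @param x numeric matrix, probes x samples.
#' @param path file path.
#' @return `read_expression_matrix()` returns a numeric matrix with probe row
#'   names and sample column names.
#' @export
write_expression_matrix <- function(x, path) {
  .assert_matrix(x, "expression matrix")
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop("expression matrix file must have a leading 'probe_id' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  m
}

#' Read and write sample metadata tables
#'
#' Tab-delimited with columns `sample_id`, `class_label`, `group`, `sex`.
#'
#' @param samples data frame of per-sample metadata.
#' @param path file path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read and write gene-set collections in GMT format
#'
#' GMT is tab-delimited: set name, description, then one gene symbol per
#' field. Descriptions default to `"na"` on write and are kept as an
#' attribute on read.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param path file path.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `"descriptions"` attribute.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Serialize a hierarchical clustering as Newick text
#'
#' @param hc an `hclust` object, e.g. from [average_linkage_cluster()].
#' @return A single Newick string (with terminating semicolon).
#' @export
as_newick <- function(hc) {
  if (!inherits(hc, "hclust")) stop("'hc' must be an hclust object")
  ape::write.tree(ape::as.phylo(hc))
}
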