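#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids with the gene id in the first column.
#' Lines starting with `#` (the header comments written by this package) are
#' skipped. Duplicate gene rows are collapsed by taking the per-sample
#' maximum, and a message records how many were collapsed.
#'
#' @param path file path
#' @param sep field separator, default tab
#' @return validated expression matrix (genes x samples)
#' @export
read_expression <- function(path, sep = "\t") {
  df <- read_tsv_checked(path, sep)
  if (ncol(df) < 2)
    stop("malformed expression file: need a gene-id column plus >=1 sample column")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric expression values in column '", names(df)[-1][bad], "'")
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    mat <- rowsum_max(mat, genes)
    genes <- rownames(mat)
    message("collapsed ", n_dup, " duplicate gene row(s) by max expression")
  } else {
    rownames(mat) <- genes
  }
  expression_matrix(mat)
}

# collapse duplicate row groups by column-wise max, preserving first-seen order
rowsum_max <- function(mat, groups) {
  u <- unique(groups)
  out <- matrix(NA_real_, length(u), ncol(mat),
                dimnames = list(u, colnames(mat)))
  for (g in u) {
    rows <- mat[groups == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2, max)
  }
  out
}

read_tsv_checked <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- tryCatch(readLines(path, n = 50L, warn = FALSE), error = function(e) character())
  first <- first[!startsWith(first, "#")]
  if (!length(first)) stop("format error: empty file: ", path)
  utils::read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an immune-cell abundance matrix from TSV
#'
#' First column `sample_id`, one column per cell type.
#'
#' @inheritParams read_expression
#' @param relative enforce rows summing to 1
#' @return validated abundance matrix (samples x cell types)
#' @export
read_abundance <- function(path, sep = "\t", relative = TRUE) {
  df <- read_tsv_checked(path, sep)
  if (names(df)[1] != "sample_id")
    stop("schema error: abundance table must start with a 'sample_id' column")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$sample_id)
  abundance_matrix(mat, relative = relative)
}

#' Read a clinical table from TSV
#' @inheritParams read_expression
#' @return validated clinical table
#' @export
read_clinical <- function(path, sep = "\t") {
  clinical_table(read_tsv_checked(path, sep))
}

#' Read gene sets in GMT format
#'
#' Standard MSigDB dialect: one set per line, `name TAB description TAB
#' gene1 TAB gene2 ...`. Duplicate genes within a set are dropped; duplicate
#' set names across lines are an error.
#'
#' @param path file path
#' @return gene-set collection (named list with a `descriptions` attribute)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("format error: empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("format error: GMT line ", short[1], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- names_
  gene_set_collection(sets, descriptions = desc)
}

#' Write gene sets in GMT format
#' @param sets gene-set collection
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a matrix as TSV with a provenance header comment
#'
#' The first line is a `#` comment recording the package version and any
#' parameter string, so every output table is self-describing; readers in
#' this package skip comment lines.
#'
#' @param mat matrix with dimnames
#' @param path output path
#' @param id_col name of the first (identifier) column
#' @param params optional parameter string recorded in the header comment
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id", params = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tiilnc ", tiilnc_version(),
                    if (nzchar(params)) paste0(" | ", params) else ""), con)
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with a provenance header comment
#' @inheritParams write_matrix_tsv
#' @param df data.frame
#' @export
write_table_tsv <- function(df, path, params = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tiilnc ", tiilnc_version(),
                    if (nzchar(params)) paste0(" | ", params) else ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
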