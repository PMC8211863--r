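#' Construct a validated expression matrix
#'
#' Expression values are genes x samples on a log2(x+1)-like scale: finite
#' and non-negative, with unique gene and sample identifiers. This
#' orientation (genes in rows) is fixed throughout the package; immune-cell
#' abundance matrices use the transposed convention (samples in rows), which
#' matches how each is consumed downstream.
#'
#' @param values numeric matrix, genes x samples
#' @param gene_ids,sample_ids optional identifier vectors; default taken from
#'   `dimnames(values)`
#' @return the validated numeric matrix with dimnames set
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  if (anyNA(values))
    stop("expression matrix contains missing values; complete data required")
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (any(values < 0))
    stop("expression values must be non-negative (log2(x+1) scale)")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

#' Construct a validated immune-cell abundance matrix
#'
#' Samples x cell types. When `relative = TRUE` (the CIBERSORT-style
#' convention) each row must sum to 1 within `tol`.
#'
#' @param values numeric matrix, samples x cell types
#' @param relative logical; enforce rows summing to 1
#' @param tol row-sum tolerance
#' @return validated numeric matrix
#' @export
abundance_matrix <- function(values, relative = TRUE, tol = 1e-6) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("abundance values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix requires sample rownames and cell-type colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate sample or cell-type ids")
  if (anyNA(values) || any(!is.finite(values)))
    stop("abundance matrix contains missing or non-finite values")
  if (any(values < 0) || any(values > 1))
    stop("abundance fractions must lie in [0, 1]")
  if (relative) {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > tol)
    if (length(bad))
      stop("abundance rows must sum to 1 (relative fractions); offending sample(s): ",
           paste(utils::head(rownames(values)[bad], 5), collapse = ", "))
  }
  values
}

#' Construct a validated clinical table
#'
#' Required columns: `sample_id`, `cancer_type`, `time` (days, >= 0) and
#' `event` (1 = death). An optional `response` column (1 = ICI responder) and
#' arbitrary additional covariate columns are carried through.
#'
#' @param df data.frame
#' @return validated data.frame
#' @export
clinical_table <- function(df) {
  req <- c("sample_id", "cancer_type", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table")
  if (any(is.na(df$time)) || any(df$time < 0))
    stop("survival time must be non-negative")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be coded 0/1")
  if ("response" %in% names(df)) {
    ok <- df$response %in% c(0, 1) | is.na(df$response)
    if (!all(ok)) stop("response must be coded 0/1 (NA allowed)")
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Construct a validated gene-set collection
#'
#' A named list of non-empty character vectors; duplicate genes within a set
#' are dropped (first occurrence kept), duplicate set names are an error.
#'
#' @param sets named list of character vectors
#' @param descriptions optional character vector of per-set descriptions
#' @return named list with a `descriptions` attribute
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (!is.null(descriptions)) {
    stopifnot(length(descriptions) == length(sets))
    attr(sets, "descriptions") <- stats::setNames(descriptions, names(sets))
  }
  sets
}

#' Align expression, clinical and abundance inputs on shared samples
#'
#' Returns each table restricted to the intersection of sample ids, together
#' with an explicit report of every id dropped from each table; samples are
#' never silently dropped by downstream stages.
#'
#' @param expr expression matrix (genes x samples) or NULL
#' @param clinical clinical table or NULL
#' @param abundance abundance matrix (samples x cell types) or NULL
#' @return list with the aligned objects, `samples` (the intersection, in
#'   expression order where available) and `dropped` (per-table id lists)
#' @export
align_samples <- function(expr = NULL, clinical = NULL, abundance = NULL) {
  ids <- list()
  if (!is.null(expr)) ids$expression <- colnames(expr)
  if (!is.null(clinical)) ids$clinical <- clinical$sample_id
  if (!is.null(abundance)) ids$abundance <- rownames(abundance)
  if (!length(ids)) stop("nothing to align")
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no shared samples across inputs")
  ref <- ids[[1]]
  common <- ref[ref %in% common]
  dropped <- lapply(ids, function(x) setdiff(x, common))
  out <- list(samples = common, dropped = dropped)
  if (!is.null(expr)) out$expression <- expr[, common, drop = FALSE]
  if (!is.null(clinical))
    out$clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  if (!is.null(abundance)) out$abundance <- abundance[common, , drop = FALSE]
  out
}
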