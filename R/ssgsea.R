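#' ssGSEA parameters
#'
#' @param tau rank-weighting exponent, default 0.25 (the conventional
#'   single-sample GSEA default); tau = 0 weights all in-set genes equally
#' @param normalize divide all enrichment scores by the global
#'   (max - min) across the whole sets x samples matrix
#' @return validated `ssgsea_params` list
#' @export
ssgsea_params <- function(tau = 0.25, normalize = TRUE) {
  if (tau < 0) stop("tau must be >= 0")
  structure(list(tau = tau, normalize = normalize), class = "ssgsea_params")
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample independently, genes are ranked by expression (average
#' ranks for ties) and walked in descending order; the enrichment score is
#' the sum over all positions of the difference between the running
#' rank-weighted fraction of in-set genes (weight rank^tau) and the running
#' unweighted fraction of out-of-set genes. Scores depend only on
#' within-sample ranks, so any monotone transform of a sample's values
#' leaves them unchanged. With `normalize`, the whole matrix is divided by
#' its global max - min.
#'
#' @param expr expression matrix (genes x samples)
#' @param sets gene-set collection; sets without overlap are skipped with a
#'   warning, a set covering every gene is an error (no out-of-set genes)
#' @param params [ssgsea_params()]
#' @return numeric matrix, sets x samples
#' @export
ssgsea <- function(expr, sets, params = ssgsea_params()) {
  genes <- rownames(expr)
  keep <- vapply(names(sets), function(nm) {
    ov <- sum(sets[[nm]] %in% genes)
    if (ov == 0) {
      warning("ssGSEA: set '", nm, "' has no overlap with the matrix; skipped")
      return(FALSE)
    }
    if (ov == length(genes))
      stop("ssGSEA: set '", nm, "' must be a proper subset of the genes")
    TRUE
  }, logical(1))
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set overlaps the expression matrix")

  in_set <- vapply(sets, function(g) genes %in% g, logical(length(genes)))
  es <- matrix(NA_real_, length(sets), ncol(expr),
               dimnames = list(names(sets), colnames(expr)))
  n_genes <- length(genes)
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, seq_along(x))        # descending; gene order breaks ties
    w_all <- r[ord]^params$tau
    for (si in seq_along(sets)) {
      ind <- in_set[ord, si]
      w <- w_all * ind
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!ind) / (n_genes - sum(ind))
      es[si, j] <- sum(p_in - p_out)
    }
  }
  if (params$normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}
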