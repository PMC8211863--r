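#' TII-lncRNA-derived immune state index (TISI)
#'
#' Per-sample arithmetic mean of the screened lncRNA panel's expression.
#' Higher TISI corresponds to the low-affinity immune phenotype. Listed
#' genes absent from the matrix are reported via warning; at least one must
#' be present.
#'
#' @param expr expression matrix (genes x samples)
#' @param tii_lncrnas character vector of panel gene ids
#' @return named numeric vector of per-sample scores
#' @export
tisi <- function(expr, tii_lncrnas) {
  present <- intersect(tii_lncrnas, rownames(expr))
  absent <- setdiff(tii_lncrnas, present)
  if (!length(present)) stop("none of the listed lncRNAs are present")
  if (length(absent))
    warning("TISI: ", length(absent), " listed lncRNA(s) absent from matrix: ",
            paste(utils::head(absent, 5), collapse = ", "))
  colMeans(expr[present, , drop = FALSE])
}

#' Cytolytic activity score (CYT)
#'
#' Geometric mean of granzyme A and perforin. Input expression is assumed
#' log2(x+1); values are back-transformed to the linear scale before the
#' geometric mean (taking it on the log scale would double-log), with a
#' small pseudocount for zeros.
#'
#' @param expr expression matrix (genes x samples), log2(x+1) scale
#' @param gzma_id,prf1_id gene ids of the two effectors
#' @param pseudocount added to each linear value, default 0.01
#' @param log2_output report the score on the log2 scale
#' @return named numeric vector of per-sample scores
#' @export
cyt <- function(expr, gzma_id = "GZMA", prf1_id = "PRF1",
                pseudocount = 0.01, log2_output = FALSE) {
  for (g in c(gzma_id, prf1_id))
    if (!g %in% rownames(expr)) stop("gene not found in matrix: ", g)
  gz <- 2^expr[gzma_id, ] - 1
  pf <- 2^expr[prf1_id, ] - 1
  s <- sqrt((gz + pseudocount) * (pf + pseudocount))
  if (log2_output) log2(s) else s
}

#' Immunologic Constant of Rejection (ICR) score
#'
#' Each signature gene is z-scored across the cohort (mean 0, sd 1); the
#' per-sample ICR is the mean of the z-scores over the available genes.
#' Zero-variance genes cannot be z-scored and are excluded with a warning.
#'
#' @param expr expression matrix (genes x samples)
#' @param icr_genes signature gene ids (20 genes in the published signature)
#' @return named numeric vector of per-sample scores (cohort mean 0)
#' @export
icr <- function(expr, icr_genes) {
  present <- intersect(icr_genes, rownames(expr))
  absent <- setdiff(icr_genes, present)
  if (!length(present)) stop("none of the ICR genes are present")
  if (length(absent))
    warning("ICR: ", length(absent), " signature gene(s) absent: ",
            paste(utils::head(absent, 5), collapse = ", "))
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning("ICR: excluding zero-variance gene(s): ",
            paste(rownames(sub)[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (!nrow(sub)) stop("no ICR genes with non-zero variance")
  }
  z <- (sub - rowMeans(sub)) / sds
  colMeans(z)
}

#' Epithelial-mesenchymal transition (EMT) score
#'
#' Per-sample Welch two-sample t-statistic contrasting the mesenchymal
#' marker genes against the epithelial marker genes:
#' (mean_M - mean_E) / sqrt(var_M/n_M + var_E/n_E). Positive scores are
#' mesenchymal-leaning; this direction is fixed so that higher EMT aligns
#' with the stromal/mesenchymal phenotype the index is meant to track.
#'
#' @param expr expression matrix (genes x samples)
#' @param epithelial,mesenchymal marker gene id vectors (>= 2 present each)
#' @return named numeric vector of per-sample t-statistics
#' @export
emt <- function(expr, epithelial, mesenchymal) {
  e <- intersect(epithelial, rownames(expr))
  m <- intersect(mesenchymal, rownames(expr))
  if (length(e) < 2 || length(m) < 2)
    stop("need >= 2 present genes in each of the epithelial and mesenchymal sets")
  E <- expr[e, , drop = FALSE]
  M <- expr[m, , drop = FALSE]
  mu_e <- colMeans(E); mu_m <- colMeans(M)
  var_e <- apply(E, 2, stats::var); var_m <- apply(M, 2, stats::var)
  denom <- sqrt(var_m / length(m) + var_e / length(e))
  t_stat <- (mu_m - mu_e) / denom
  t_stat[denom == 0 & mu_m == mu_e] <- 0   # identical values: no contrast
  t_stat
}

#' Assemble the per-sample score table
#'
#' Convenience wrapper computing TISI plus any of CYT, ICR, EMT and ssGSEA
#' scores for which the needed gene lists are supplied. Gene sets with the
#' reserved names EPITHELIAL, MESENCHYMAL, ICR drive the corresponding
#' indices; every other set is scored by ssGSEA.
#'
#' @param expr expression matrix (genes x samples)
#' @param tii_lncrnas TISI panel gene ids
#' @param gene_sets optional gene-set collection
#' @param gzma_id,prf1_id optional CYT effector ids (NULL skips CYT)
#' @param ssgsea_opts [ssgsea_params()] options for the ssGSEA-scored sets
#' @return data.frame, one row per sample, one column per score
#' @export
score_samples <- function(expr, tii_lncrnas, gene_sets = NULL,
                          gzma_id = NULL, prf1_id = NULL,
                          ssgsea_opts = ssgsea_params()) {
  out <- data.frame(sample_id = colnames(expr),
                    tisi = unname(tisi(expr, tii_lncrnas)),
                    stringsAsFactors = FALSE)
  if (!is.null(gzma_id) && !is.null(prf1_id))
    out$cyt <- unname(cyt(expr, gzma_id, prf1_id))
  if (!is.null(gene_sets)) {
    if ("ICR" %in% names(gene_sets))
      out$icr <- unname(icr(expr, gene_sets$ICR))
    if (all(c("EPITHELIAL", "MESENCHYMAL") %in% names(gene_sets)))
      out$emt <- unname(emt(expr, gene_sets$EPITHELIAL, gene_sets$MESENCHYMAL))
    other <- setdiff(names(gene_sets), c("ICR", "EPITHELIAL", "MESENCHYMAL"))
    if (length(other)) {
      es <- ssgsea(expr, gene_sets[other], params = ssgsea_opts)
      for (nm in rownames(es)) out[[paste0("es_", nm)]] <- es[nm, ]
    }
  }
  out
}
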