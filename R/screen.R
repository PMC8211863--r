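#' Screening parameters for the three-step TII-lncRNA framework
#'
#' Defaults follow the published operating point: lncRNAs with no expression
#' in more than 20% of samples are removed; correlation steps require
#' |PCC| >= 0.3 with P < 0.05; infiltration groups are the top and bottom
#' quartiles of a cell type's abundance; differential expression requires a
#' two-sided Wilcoxon rank-sum P < 0.05.
#'
#' @param max_zero_fraction genes with a larger fraction of zero values are
#'   removed (strictly greater; exactly this fraction is kept)
#' @param pcc_threshold minimum Pearson correlation for steps 1-2
#' @param p_threshold correlation p-value cutoff (strict `<`)
#' @param quartile fraction of samples in each infiltration group
#' @param de_p_threshold Wilcoxon p-value cutoff for step 3
#' @param use_absolute_pcc if TRUE (default) the threshold applies to |PCC|,
#'   so both infiltration-promoting and -suppressing lncRNAs qualify
#' @param require_same_cell_type if TRUE (default) the step-2 correlation and
#'   step-3 differential expression must hold for the same cell type
#' @param min_marker_hits minimum number of step-1 marker genes that must
#'   pass for a lncRNA to qualify
#' @param multiple_testing "none" (default, matching the published screen) or
#'   "BH" to Benjamini-Hochberg-adjust p-values within each step
#' @return validated `screen_params` list
#' @export
screen_params <- function(max_zero_fraction = 0.20, pcc_threshold = 0.30,
                          p_threshold = 0.05, quartile = 0.25,
                          de_p_threshold = 0.05, use_absolute_pcc = TRUE,
                          require_same_cell_type = TRUE, min_marker_hits = 1,
                          multiple_testing = c("none", "BH")) {
  multiple_testing <- match.arg(multiple_testing)
  p <- as.list(environment())
  for (nm in c("pcc_threshold", "p_threshold", "de_p_threshold"))
    if (p[[nm]] <= 0 || p[[nm]] > 1) stop(nm, " must lie in (0, 1]")
  if (p$max_zero_fraction < 0 || p$max_zero_fraction >= 1)
    stop("max_zero_fraction must lie in [0, 1)")
  if (p$quartile <= 0 || p$quartile >= 0.5)
    stop("quartile must lie in (0, 0.5)")
  class(p) <- "screen_params"
  p
}

#' Remove lncRNAs with no expression in too many samples
#'
#' A gene is kept when its fraction of samples with expression <= 0 is at
#' most `max_zero_fraction`; only strictly larger fractions are removed
#' (a gene at exactly the boundary is retained).
#'
#' @param expr expression matrix (genes x samples)
#' @param max_zero_fraction removal threshold, default 0.20
#' @return the filtered expression matrix
#' @export
filter_expressed <- function(expr, max_zero_fraction = 0.20) {
  zero_frac <- rowMeans(expr <= 0)
  keep <- zero_frac <= max_zero_fraction
  if (!any(keep)) stop("all genes filtered at max_zero_fraction = ",
                       max_zero_fraction)
  expr[keep, , drop = FALSE]
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' p is computed from t = r * sqrt((n-2) / (1-r^2)) on n-2 degrees of
#' freedom. A constant input vector makes the correlation undefined; the
#' pair is then reported as r = 0, p = 1 with `degenerate = TRUE` rather
#' than propagating NaN.
#'
#' @param x,y numeric vectors of equal length n >= 3
#' @return list with `pcc`, `p_value`, `n`, `degenerate`
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pcc = 0, p_value = 1, n = n, degenerate = TRUE))
  r <- min(1, max(-1, stats::cor(x, y)))
  p <- pcc_pvalue(r, n)
  list(pcc = r, p_value = p, n = n, degenerate = FALSE)
}

# two-sided p of the Pearson t-transform; vectorised over r
pcc_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

# all-pairs correlation records; `partners` is samples x partner columns
# (marker genes transposed, or abundance cell types)
correlation_records <- function(lnc_expr, partners) {
  n <- ncol(lnc_expr)
  x <- t(lnc_expr)                       # samples x lncRNAs
  sd_x <- apply(x, 2, stats::sd)
  sd_y <- apply(partners, 2, stats::sd)
  r <- matrix(0, ncol(x), ncol(partners),
              dimnames = list(colnames(x), colnames(partners)))
  ok <- sd_x > 0
  ok_y <- sd_y > 0
  if (any(ok) && any(ok_y))
    r[ok, ok_y] <- stats::cor(x[, ok, drop = FALSE],
                              partners[, ok_y, drop = FALSE])
  r[!is.finite(r)] <- 0
  p <- pcc_pvalue(r, n)
  degenerate <- outer(!ok, !ok_y, `|`)
  p[degenerate] <- 1
  data.frame(
    lncrna_id = rep(rownames(r), times = ncol(r)),
    partner_id = rep(colnames(r), each = nrow(r)),
    pcc = as.vector(r),
    p_value = as.vector(p),
    n = n,
    degenerate = as.vector(degenerate),
    stringsAsFactors = FALSE
  )
}

# threshold a correlation-record table; returns the records flagged pass
mark_correlation_pass <- function(records, params) {
  pv <- records$p_value
  if (params$multiple_testing == "BH") pv <- stats::p.adjust(pv, "BH")
  eff <- if (params$use_absolute_pcc) abs(records$pcc) else records$pcc
  # tiny epsilon so an exact linear duplicate (r = 1 up to float error)
  # clears a threshold of exactly 1
  records$pass <- !records$degenerate &
    eff >= params$pcc_threshold - 1e-12 & pv < params$p_threshold
  records
}

#' Step 1: co-expression with immune marker genes
#'
#' Every lncRNA is correlated with every immune marker gene; a lncRNA
#' qualifies when at least `min_marker_hits` markers reach the correlation
#' and significance thresholds.
#'
#' @param lnc_expr lncRNA expression (genes x samples)
#' @param marker_expr immune-marker expression (genes x samples), same samples
#' @param params [screen_params()]
#' @return list with `records` (all pairs, pass-flagged) and `passed`
#'   (character vector of qualifying lncRNA ids)
#' @export
step1_marker_correlation <- function(lnc_expr, marker_expr,
                                     params = screen_params()) {
  if (nrow(marker_expr) == 0) stop("marker matrix is empty")
  shared <- intersect(colnames(lnc_expr), colnames(marker_expr))
  if (!length(shared)) stop("no shared samples between lncRNA and marker matrices")
  rec <- correlation_records(lnc_expr[, shared, drop = FALSE],
                             t(marker_expr[, shared, drop = FALSE]))
  rec <- mark_correlation_pass(rec, params)
  hits <- tapply(rec$pass, rec$lncrna_id, sum)
  passed <- rownames(lnc_expr)[rownames(lnc_expr) %in%
                                 names(hits)[hits >= params$min_marker_hits]]
  list(records = rec, passed = passed)
}

#' Step 2: correlation with immune-cell abundance
#'
#' Candidates from step 1 are correlated with each cell type's abundance
#' fraction; a lncRNA qualifies when at least one cell type reaches the
#' thresholds. The qualifying cell types are retained for the step-3 link.
#'
#' @param lnc_expr candidate lncRNA expression (genes x samples)
#' @param abundance abundance matrix (samples x cell types)
#' @param params [screen_params()]
#' @return list with `records`, `passed` and `passed_cell_types` (named list
#'   of qualifying cell types per passed lncRNA)
#' @export
step2_abundance_correlation <- function(lnc_expr, abundance,
                                        params = screen_params()) {
  shared <- intersect(colnames(lnc_expr), rownames(abundance))
  if (!length(shared)) stop("no shared samples between lncRNA and abundance matrices")
  rec <- correlation_records(lnc_expr[, shared, drop = FALSE],
                             abundance[shared, , drop = FALSE])
  rec <- mark_correlation_pass(rec, params)
  pass_rec <- rec[rec$pass, , drop = FALSE]
  passed_cell_types <- split(pass_rec$partner_id, pass_rec$lncrna_id)
  passed <- rownames(lnc_expr)[rownames(lnc_expr) %in% names(passed_cell_types)]
  list(records = rec, passed = passed,
       passed_cell_types = passed_cell_types[passed])
}

#' Step 3: differential expression between infiltration quartile groups
#'
#' For each cell type, samples are ranked by abundance; the top quartile
#' forms the high-infiltration group and the bottom quartile the low group
#' (ties at a cut resolved deterministically by sample id). Each candidate
#' lncRNA is compared between groups by a two-sided Wilcoxon rank-sum test
#' (exact when the smaller group has <= 10 samples and there are no ties,
#' otherwise the normal approximation with tie and continuity correction).
#'
#' @param lnc_expr candidate lncRNA expression (genes x samples)
#' @param abundance abundance matrix (samples x cell types)
#' @param params [screen_params()]
#' @param cell_types optional subset of cell types to test (default all)
#' @return data.frame of DE records: lncrna_id, cell_type, statistic (W),
#'   p_value, direction, n_high, n_low
#' @export
step3_quartile_de <- function(lnc_expr, abundance, params = screen_params(),
                              cell_types = colnames(abundance)) {
  shared <- intersect(colnames(lnc_expr), rownames(abundance))
  if (!length(shared)) stop("no shared samples between lncRNA and abundance matrices")
  lnc <- lnc_expr[, shared, drop = FALSE]
  ab <- abundance[shared, , drop = FALSE]
  n <- length(shared)
  k <- floor(params$quartile * n)
  out <- vector("list", length(cell_types))
  for (ci in seq_along(cell_types)) {
    ct <- cell_types[ci]
    if (k < 2) {
      warning("cell type ", ct, " skipped: quartile group size ", k, " < 2")
      next
    }
    ord <- order(ab[, ct], rownames(ab))   # ties broken by sample id
    low_idx <- ord[seq_len(k)]
    high_idx <- ord[(n - k + 1):n]
    recs <- lapply(rownames(lnc), function(g) {
      hi <- lnc[g, high_idx]
      lo <- lnc[g, low_idx]
      wt <- wilcox_rank_sum(hi, lo)
      data.frame(lncrna_id = g, cell_type = ct, statistic = wt$statistic,
                 p_value = wt$p_value,
                 direction = if (mean(hi) >= mean(lo)) "up_in_high" else "up_in_low",
                 n_high = length(hi), n_low = length(lo),
                 stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(lncrna_id = character(), cell_type = character(),
                      statistic = numeric(), p_value = numeric(),
                      direction = character(), n_high = integer(),
                      n_low = integer(), stringsAsFactors = FALSE)
  res
}

# two-sided Wilcoxon rank-sum: exact for small tie-free groups, otherwise
# normal approximation with tie correction and continuity correction
wilcox_rank_sum <- function(x, y) {
  if (stats::sd(c(x, y)) == 0)   # identical values in both groups: no signal
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 10 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Run the full three-step TII-lncRNA screen
#'
#' Composition: expression filter, then marker-gene correlation (step 1),
#' then abundance correlation on the survivors (step 2), then quartile
#' differential expression on the remaining candidates (step 3). With
#' `require_same_cell_type` the step-2 and step-3 evidence must name the
#' same cell type for at least one cell type.
#'
#' @param lnc_expr lncRNA expression matrix (genes x samples)
#' @param marker_expr immune marker expression matrix (genes x samples)
#' @param abundance abundance matrix (samples x cell types)
#' @param params [screen_params()]
#' @return a `screen_result` list: `passed_lncrnas`, `evidence` (step1/2/3
#'   record tables), `counts` (survivors per stage), `linked_cell_type`
#'   (first qualifying cell type per passed lncRNA) and the echoed params
#' @export
run_screen <- function(lnc_expr, marker_expr, abundance,
                       params = screen_params()) {
  al <- align_samples(expr = lnc_expr, abundance = abundance)
  lnc_expr <- al$expression
  abundance <- al$abundance
  expressed <- filter_expressed(lnc_expr, params$max_zero_fraction)

  s1 <- step1_marker_correlation(expressed, marker_expr, params)
  s1_expr <- expressed[s1$passed, , drop = FALSE]

  if (length(s1$passed)) {
    s2 <- step2_abundance_correlation(s1_expr, abundance, params)
  } else {
    s2 <- list(records = NULL, passed = character(), passed_cell_types = list())
  }
  s2_expr <- expressed[s2$passed, , drop = FALSE]

  if (length(s2$passed)) {
    s3 <- step3_quartile_de(s2_expr, abundance, params)
  } else {
    s3 <- step3_quartile_de(expressed[0, , drop = FALSE], abundance, params)
  }

  pv3 <- s3$p_value
  if (length(pv3) && params$multiple_testing == "BH")
    pv3 <- stats::p.adjust(pv3, "BH")
  s3$pass <- if (length(pv3)) pv3 < params$de_p_threshold else logical(0)

  passed <- character()
  linked <- character()
  for (g in s2$passed) {
    de_ok <- s3[s3$lncrna_id == g & s3$pass, , drop = FALSE]
    if (!nrow(de_ok)) next
    if (params$require_same_cell_type) {
      common <- intersect(de_ok$cell_type, s2$passed_cell_types[[g]])
      if (!length(common)) next
      linked[g] <- common[1]
    } else {
      linked[g] <- de_ok$cell_type[1]
    }
    passed <- c(passed, g)
  }

  structure(list(
    passed_lncrnas = passed,
    linked_cell_type = linked,
    evidence = list(step1 = s1$records, step2 = s2$records, step3 = s3),
    counts = c(input = nrow(lnc_expr), expressed = nrow(expressed),
               step1 = length(s1$passed), step2 = length(s2$passed),
               step3 = length(passed)),
    params = params
  ), class = "screen_result")
}

#' Summarise a screen result as one row per lncRNA
#'
#' @param result a `screen_result`
#' @return data.frame with pass flags, best absolute PCCs/p-values per step
#'   and the linked cell type
#' @export
screen_summary <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  s1 <- result$evidence$step1
  ids <- unique(s1$lncrna_id)
  best <- function(rec, id) {
    r <- rec[rec$lncrna_id == id, , drop = FALSE]
    if (!nrow(r)) return(c(NA_real_, NA_real_))
    i <- which.max(abs(r$pcc))
    c(r$pcc[i], r$p_value[i])
  }
  s2 <- result$evidence$step2
  s3 <- result$evidence$step3
  rows <- lapply(ids, function(id) {
    b1 <- best(s1, id)
    b2 <- if (!is.null(s2)) best(s2, id) else c(NA_real_, NA_real_)
    de <- s3[s3$lncrna_id == id, , drop = FALSE]
    de_p <- if (nrow(de)) min(de$p_value) else NA_real_
    data.frame(lncrna_id = id,
               best_marker_pcc = b1[1], best_marker_p = b1[2],
               best_abundance_pcc = b2[1], best_abundance_p = b2[2],
               best_de_p = de_p,
               passed = id %in% result$passed_lncrnas,
               linked_cell_type = if (id %in% names(result$linked_cell_type))
                 result$linked_cell_type[[id]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
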