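#' Consensus clustering parameters
#'
#' Defaults mirror the conventional consensus-clustering settings: 100
#' subsampling rounds at 80% of samples, K-means with Euclidean distance and
#' 10 random restarts. Only samples are subsampled, never features.
#'
#' @param k_range integer cluster numbers to evaluate (all >= 2)
#' @param n_resamples subsampling rounds per k
#' @param subsample_fraction fraction of samples drawn (without replacement)
#' @param kmeans_restarts random K-means initialisations per round (best
#'   within-cluster sum of squares kept)
#' @param seed master seed; per-k streams derive from it
#' @return validated `consensus_params` list
#' @export
consensus_params <- function(k_range = 2:6, n_resamples = 100,
                             subsample_fraction = 0.8, kmeans_restarts = 10,
                             seed = 1) {
  if (!length(k_range) || any(k_range < 2)) stop("k_range must contain integers >= 2")
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stop("subsample_fraction must lie in (0, 1)")
  structure(list(k_range = sort(unique(as.integer(k_range))),
                 n_resamples = n_resamples,
                 subsample_fraction = subsample_fraction,
                 kmeans_restarts = kmeans_restarts, seed = seed),
            class = "consensus_params")
}

#' Consensus K-means clustering over subsampled cohorts
#'
#' For each k, `n_resamples` rounds draw `ceiling(fraction * n)` samples
#' without replacement and partition them by K-means (Euclidean); the
#' consensus matrix entry M[i, j] is the fraction of co-sampled rounds in
#' which samples i and j fell in the same cluster. Final per-k assignments
#' come from average-linkage agglomerative clustering of 1 - M cut at k.
#'
#' @param expr_subset expression matrix (features x samples), typically
#'   restricted to the screened TII-lncRNAs
#' @param params [consensus_params()]
#' @return a `consensus_result` list: `consensus` (per-k matrices),
#'   `assignments` (per-k integer vectors), `cdf_area` and `delta_area`
#'   per k, `selected_k`, plus co-sampled/co-clustered counts for audit
#' @export
consensus_cluster <- function(expr_subset, params = consensus_params()) {
  X <- t(expr_subset)                    # samples x features
  n <- nrow(X)
  k_max <- max(params$k_range)
  sub_n <- ceiling(params$subsample_fraction * n)
  if (k_max > sub_n) stop("config error: k exceeds the subsample size")
  if (n < 3 * k_max)
    stop("need at least 3 samples per cluster at the largest k")

  consensus <- list(); assignments <- list()
  co_clustered <- list(); co_sampled <- list()
  for (k in params$k_range) {
    set.seed(derive_seed(params$seed, paste0("consensus-k", k)))
    C <- matrix(0, n, n); I <- matrix(0, n, n)
    for (b in seq_len(params$n_resamples)) {
      idx <- sort(sample.int(n, sub_n))
      km <- stats::kmeans(X[idx, , drop = FALSE], centers = k,
                          nstart = params$kmeans_restarts, iter.max = 50)
      I[idx, idx] <- I[idx, idx] + 1
      for (cl in seq_len(k)) {
        members <- idx[km$cluster == cl]
        C[members, members] <- C[members, members] + 1
      }
    }
    M <- ifelse(I > 0, C / I, 0)
    diag(M) <- 1
    dimnames(M) <- list(rownames(X), rownames(X))
    hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
    a <- stats::cutree(hc, k = k)
    kk <- as.character(k)
    consensus[[kk]] <- M; assignments[[kk]] <- a
    co_clustered[[kk]] <- C; co_sampled[[kk]] <- I
  }

  cdf_area <- vapply(consensus, consensus_cdf_area, numeric(1))
  res <- structure(list(consensus = consensus, assignments = assignments,
                        cdf_area = cdf_area, k_range = params$k_range,
                        co_clustered = co_clustered, co_sampled = co_sampled,
                        params = params),
                   class = "consensus_result")
  res$delta_area <- consensus_delta_area(res)
  res$selected_k <- select_k(res)
  res
}

# area under the empirical CDF of the off-diagonal consensus values,
# integrated over the full [0, 1] consensus support
consensus_cdf_area <- function(M, n_bins = 100) {
  v <- M[upper.tri(M)]
  if (!length(v)) return(0)
  xs <- seq(0, 1, length.out = n_bins + 1)
  cdf <- stats::ecdf(v)
  sum(cdf(xs[-length(xs)]) * diff(xs))
}

consensus_delta_area <- function(result) {
  A <- result$cdf_area
  ks <- result$k_range
  delta <- numeric(length(ks))
  delta[1] <- A[1]
  if (length(ks) > 1)
    for (i in 2:length(ks)) delta[i] <- (A[i] - A[i - 1]) / A[i - 1]
  stats::setNames(delta, as.character(ks))
}

#' Select the number of clusters by the CDF delta-area rule
#'
#' A(k) is the area under the empirical CDF of off-diagonal consensus
#' values; the relative increase Delta(k) = (A(k) - A(k-1)) / A(k-1) (with
#' Delta at the smallest k equal to A itself) measures the stability gained
#' by allowing one more cluster. The selected k is the largest k whose
#' Delta still reaches `delta_threshold`; if none does, the smallest k in
#' the range is returned.
#'
#' @param result a `consensus_result`
#' @param delta_threshold minimum relative area gain, default 0.1
#' @return the selected integer k
#' @export
select_k <- function(result, delta_threshold = 0.1) {
  delta <- result$delta_area %||% consensus_delta_area(result)
  ks <- result$k_range
  ok <- which(delta >= delta_threshold)
  if (!length(ok)) return(min(ks))
  ks[max(ok)]
}

#' Cancer-type composition enrichment of clusters
#'
#' For cancer type t and cluster c: the enrichment score is the
#' fold-enrichment ES = (n_tc / n_c) / (n_t / N) and the p-value the
#' upper-tail hypergeometric probability P[X >= n_tc] with X ~
#' Hypergeometric(N, n_t, n_c). Benjamini-Hochberg-adjusted p-values across
#' the whole table are reported alongside.
#'
#' @param assignments cluster labels (vector, one per sample)
#' @param cancer_types cancer-type labels (same length/order)
#' @return data.frame with one row per (cancer_type, cluster):
#'   n_tc, n_t, n_c, N, es, es_defined, p_value, p_adj
#' @export
composition_enrichment <- function(assignments, cancer_types) {
  stopifnot(length(assignments) == length(cancer_types))
  N <- length(assignments)
  clusters <- sort(unique(assignments))
  types <- sort(unique(cancer_types))
  rows <- list()
  for (t in types) {
    n_t <- sum(cancer_types == t)
    for (cl in clusters) {
      n_c <- sum(assignments == cl)
      n_tc <- sum(cancer_types == t & assignments == cl)
      es <- if (n_c > 0) (n_tc / n_c) / (n_t / N) else NA_real_
      p <- stats::phyper(n_tc - 1, n_t, N - n_t, n_c, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cancer_type = t, cluster = cl, n_tc = n_tc, n_t = n_t, n_c = n_c,
        N = N, es = es, es_defined = n_c > 0, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Subsample robustness of the consensus partition
#'
#' Repeatedly retains a fraction of the samples, re-runs the full consensus
#' clustering on the retained set, and reports the adjusted Rand index
#' between the trial assignment and the full-data assignment restricted to
#' the retained samples (both at the full-data selected k), plus whether the
#' trial's own selected k agreed.
#'
#' @param expr_subset expression matrix (features x samples)
#' @param params [consensus_params()]
#' @param retain_fractions fractions of samples retained per trial
#' @param n_trials trials per fraction
#' @param reference optional precomputed full-data `consensus_result`
#' @return data.frame: retain_fraction, trial, ari, selected_k, k_agrees
#' @export
robustness_check <- function(expr_subset, params = consensus_params(),
                             retain_fractions = c(0.6, 0.4), n_trials = 20,
                             reference = NULL) {
  if (is.null(reference)) reference <- consensus_cluster(expr_subset, params)
  k_ref <- reference$selected_k
  full_assign <- reference$assignments[[as.character(k_ref)]]
  n <- ncol(expr_subset)
  rows <- list()
  for (f in retain_fractions) {
    for (tr in seq_len(n_trials)) {
      set.seed(derive_seed(params$seed, sprintf("robust-%g-%d", f, tr)))
      keep <- sort(sample.int(n, round(f * n)))
      if (length(keep) < 3 * max(params$k_range)) {
        rows[[length(rows) + 1L]] <- data.frame(
          retain_fraction = f, trial = tr, ari = NA_real_,
          selected_k = NA_integer_, k_agrees = NA, skipped = TRUE)
        next
      }
      sub_params <- params
      sub_params$seed <- derive_seed(params$seed, sprintf("robust-run-%g-%d", f, tr))
      trial <- consensus_cluster(expr_subset[, keep, drop = FALSE], sub_params)
      trial_assign <- trial$assignments[[as.character(k_ref)]]
      rows[[length(rows) + 1L]] <- data.frame(
        retain_fraction = f, trial = tr,
        ari = mclust::adjustedRandIndex(trial_assign, full_assign[keep]),
        selected_k = trial$selected_k,
        k_agrees = trial$selected_k == k_ref, skipped = FALSE)
    }
  }
  do.call(rbind, rows)
}
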