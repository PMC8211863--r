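# Independent oracles used to cross-check the package implementations.
# Each is written as a direct, naive computation of the defining formula,
# deliberately sharing no code with the functions under test.

# ssGSEA enrichment score by explicit position-by-position summation
oracle_ssgsea_es <- function(x, set_genes, tau) {
  genes <- names(x)
  ord_genes <- genes[order(-x, seq_along(x))]
  rk <- rank(x, ties.method = "average")
  in_set <- ord_genes %in% set_genes
  m <- sum(in_set)
  den <- sum(rk[ord_genes[in_set]]^tau)
  num <- 0; n_out <- 0; es <- 0
  for (i in seq_along(ord_genes)) {
    if (in_set[i]) num <- num + rk[ord_genes[i]]^tau else n_out <- n_out + 1
    es <- es + num / den - n_out / (length(genes) - m)
  }
  unname(es)
}

# upper-tail hypergeometric probability by summing the exact mass
oracle_hyper_upper <- function(n_tc, n_t, n_c, N) {
  ks <- max(n_tc, max(0, n_c - (N - n_t))):min(n_t, n_c)
  if (n_tc > min(n_t, n_c)) return(0)
  sum(choose(n_t, ks) * choose(N - n_t, n_c - ks)) / choose(N, n_c)
}

# upper-tail hypergeometric probability by enumerating every subset
oracle_hyper_enum <- function(n_tc, n_t, n_c, N) {
  subsets <- utils::combn(N, n_c)
  hits <- colSums(subsets <= n_t)   # items 1..n_t are the "type" items
  mean(hits >= n_tc)
}

# two-group log-rank chi-square from the observed/expected table
oracle_logrank_chi2 <- function(times, events, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  tu <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in tu) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# DerSimonian-Laird pooling from the closed form
oracle_dl_meta <- function(y, se) {
  w <- 1 / se^2
  yb <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yb)^2)
  k <- length(y)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(pooled = sum(ws * y) / sum(ws), se = 1 / sqrt(sum(ws)),
       tau2 = tau2, Q = Q)
}

# AUC by exhaustive pair counting
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# two-sided permutation p-value for the Pearson correlation
oracle_pearson_perm_p <- function(x, y, n_perm = 1e5, seed = 99) {
  set.seed(seed)
  r_obs <- abs(cor(x, y))
  perms <- replicate(n_perm, sample(y))
  r_perm <- abs(as.vector(cor(x, perms)))
  mean(r_perm >= r_obs - 1e-12)
}

# small standard cohort used across tests (A1-scale conditions)
test_cohort <- function(seed = 7, ...) {
  simulate_cohort(sim_config(seed = seed, ...))
}

split_cohort_expr <- function(cohort) {
  lnc_ids <- cohort$truth$gene_id
  list(lnc = cohort$expression[lnc_ids, , drop = FALSE],
       markers = cohort$expression[setdiff(rownames(cohort$expression),
                                           lnc_ids), , drop = FALSE])
}
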