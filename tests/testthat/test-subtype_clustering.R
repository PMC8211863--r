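test_that("consensus matrix entries are valid and the single-run limit is 0/1 co-membership", {
  sim <- simulate_clustered_expression(2, 15, 8, separation = 6, seed = 4)
  p <- consensus_params(k_range = 2, n_resamples = 1,
                        subsample_fraction = 0.999, seed = 1)
  res <- consensus_cluster(sim$expression, p)
  M <- res$consensus[["2"]]
  expect_true(all(M %in% c(0, 1)))
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 1))

  # limiting case: consensus equals the co-membership of one K-means run
  a <- res$assignments[["2"]]
  expect_identical(unname(M), unname(outer(a, a, `==`) * 1))
})

test_that("consensus entries lie in [0,1], are symmetric, and permute with samples", {
  sim <- simulate_clustered_expression(2, 12, 6, separation = 5, seed = 6)
  p <- consensus_params(k_range = 2:3, n_resamples = 30, seed = 9)
  res <- consensus_cluster(sim$expression, p)
  for (k in c("2", "3")) {
    M <- res$consensus[[k]]
    expect_true(all(M >= 0 & M <= 1))
    expect_true(isSymmetric(M))
    expect_equal(unname(diag(M)), rep(1, ncol(sim$expression)))
  }
})

test_that("three well-separated clusters are recovered with k = 3 and high ARI", {
  sim <- simulate_clustered_expression(3, 50, 20, separation = 6, seed = 11)
  res <- consensus_cluster(sim$expression,
                           consensus_params(k_range = 2:6, seed = 3))
  expect_identical(res$selected_k, 3L)
  a <- res$assignments[["3"]]
  expect_gte(mclust::adjustedRandIndex(a, sim$labels), 0.95)
  # consensus within planted clusters is high
  M <- res$consensus[["3"]]
  within <- M[outer(sim$labels, sim$labels, `==`) & upper.tri(M)]
  expect_gte(mean(within >= 0.9), 0.9)
})

test_that("pure noise yields unstable clusters with shrinking delta-area gains", {
  # Consensus clustering is known to report apparent structure on
  # unstructured data; the honest null signatures are (i) strictly
  # shrinking delta-area gains, (ii) low within-cluster consensus compared
  # with genuinely clustered data of the same size.
  set.seed(12)
  noise <- matrix(rnorm(10 * 60), 10, 60,
                  dimnames = list(sprintf("F%02d", 1:10),
                                  sprintf("S%02d", 1:60)))
  noise <- expression_matrix(noise - min(noise))
  p <- consensus_params(k_range = 2:5, n_resamples = 50, seed = 5)
  res <- consensus_cluster(noise, p)
  expect_true(all(diff(res$delta_area) < 0))

  within_consensus <- function(r, k) {
    a <- r$assignments[[as.character(k)]]
    M <- r$consensus[[as.character(k)]]
    mean(M[outer(a, a, `==`) & upper.tri(M)])
  }
  sim <- simulate_clustered_expression(3, 20, 10, separation = 6, seed = 12)
  res_struct <- consensus_cluster(sim$expression, p)
  expect_gte(within_consensus(res_struct, 3), 0.9)
  expect_lt(within_consensus(res, 3), within_consensus(res_struct, 3) - 0.2)
})

test_that("delta-threshold boundaries behave as documented", {
  sim <- simulate_clustered_expression(3, 20, 10, separation = 6, seed = 7)
  res <- consensus_cluster(sim$expression,
                           consensus_params(k_range = 2:5,
                                            n_resamples = 30, seed = 2))
  expect_identical(select_k(res, delta_threshold = 0), 5L)
  expect_identical(select_k(res, delta_threshold = Inf), 2L)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # worked example: N=20, n_t=5, n_c=4, n_tc=4
  assignments <- rep(c(1, 2), c(4, 16))
  types <- c(rep("T", 4), "T", rep("O", 15))   # all 4 of cluster 1 are type T
  tab <- composition_enrichment(assignments, types)
  row <- tab[tab$cancer_type == "T" & tab$cluster == 1, ]
  expect_equal(row$es, (4 / 4) / (5 / 20))
  expect_equal(row$p_value, 5 / 4845, tolerance = 1e-12)
  expect_equal(row$p_value, oracle_hyper_enum(4, 5, 4, 20), tolerance = 1e-12)

  # zero overlap: upper tail including 0 is exactly 1
  row0 <- tab[tab$cancer_type == "O" & tab$cluster == 1, ]
  expect_identical(row0$n_tc, 0L)
  expect_equal(row0$p_value, 1)

  # no-enrichment case: n_tc = n_t * n_c / N gives ES = 1
  a2 <- rep(c(1, 2), each = 10)
  t2 <- rep(c("X", "Y"), 10)
  tab2 <- composition_enrichment(a2, t2)
  expect_true(all(abs(tab2$es - 1) < 1e-12))

  # row totals: sum over clusters of n_tc equals n_t
  agg <- tapply(tab$n_tc, tab$cancer_type, sum)
  expect_equal(as.vector(agg[c("O", "T")]), c(15, 5))
})

test_that("hypergeometric p equals the exact mass sum across a full small grid", {
  for (N in c(6, 11, 17, 20)) {
    for (n_t in c(1, floor(N / 3), floor(N / 2))) {
      for (n_c in c(1, floor(N / 4), floor(N / 2))) {
        if (n_t < 1 || n_c < 1) next
        for (n_tc in 0:min(n_t, n_c)) {
          p_pkg <- stats::phyper(n_tc - 1, n_t, N - n_t, n_c,
                                 lower.tail = FALSE)
          expect_equal(p_pkg, oracle_hyper_upper(n_tc, n_t, n_c, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d n_t=%d n_c=%d n_tc=%d",
                                       N, n_t, n_c, n_tc))
        }
      }
    }
  }
})

test_that("ES identity: the abundance-weighted mean of fold-enrichments is 1 per cluster", {
  set.seed(8)
  assignments <- sample(1:3, 120, replace = TRUE)
  types <- sample(LETTERS[1:5], 120, replace = TRUE)
  tab <- composition_enrichment(assignments, types)
  for (cl in unique(assignments)) {
    sub <- tab[tab$cluster == cl, ]
    expect_equal(sum(sub$n_t / sub$N * sub$es), 1, tolerance = 1e-12)
  }
})

test_that("robustness check reports near-perfect ARI on clean clusters and ~0 on noise", {
  sim <- simulate_clustered_expression(3, 40, 15, separation = 6, seed = 21)
  p <- consensus_params(k_range = 2:4, n_resamples = 40, seed = 13)
  ref <- consensus_cluster(sim$expression, p)
  rb <- robustness_check(sim$expression, p, retain_fractions = 0.6,
                         n_trials = 5, reference = ref)
  expect_gte(mean(rb$ari), 0.9)

  # retain everything: same partition up to labels, ARI exactly 1
  rb1 <- robustness_check(sim$expression, p, retain_fractions = 0.999,
                          n_trials = 2, reference = ref)
  expect_true(all(rb1$ari == 1))
})
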