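toy_expr <- function(values, genes, samples) {
  expression_matrix(matrix(values, length(genes), length(samples),
                           dimnames = list(genes, samples)))
}

test_that("TISI is the panel mean, linear in constant shifts", {
  m <- toy_expr(c(2, 4, 9, 1, 3, 7), c("L1", "L2", "G1"), c("s1", "s2"))
  expect_equal(unname(tisi(m, c("L1", "L2"))), c(3, 2))
  shifted <- expression_matrix(m + 1.5)
  expect_equal(tisi(shifted, c("L1", "L2")), tisi(m, c("L1", "L2")) + 1.5)
  expect_equal(tisi(m, "L2"), m["L2", ])
  expect_warning(tisi(m, c("L1", "MISSING")), "absent")
  expect_error(tisi(m, "NOPE"), "none")
})

test_that("CYT is the geometric mean of back-transformed effectors", {
  # linear GZMA = 4, PRF1 = 16 <-> log2(x+1) = log2(5), log2(17)
  m <- toy_expr(c(log2(5), log2(17)), c("GZMA", "PRF1"), "s1")
  expect_equal(unname(cyt(m, pseudocount = 0)), 8)
  v <- toy_expr(c(3, 3), c("GZMA", "PRF1"), "s1")
  expect_equal(unname(cyt(v, pseudocount = 0)), 2^3 - 1)
  m2 <- toy_expr(c(2, 4), c("GZMA", "PRF1"), "s1")
  expect_equal(unname(cyt(m2, pseudocount = 0.01)), sqrt(3.01 * 15.01),
               tolerance = 1e-12)
  expect_error(cyt(m2, gzma_id = "ABSENT"), "ABSENT")
})

test_that("ICR matches hand-computed z-scores and is cohort-centred", {
  vals <- matrix(c(1, 4, 7,
                   2, 2, 8), 2, 3, byrow = TRUE,
                 dimnames = list(c("I1", "I2"), c("s1", "s2", "s3")))
  m <- expression_matrix(vals)
  z1 <- (vals[1, ] - mean(vals[1, ])) / sd(vals[1, ])
  z2 <- (vals[2, ] - mean(vals[2, ])) / sd(vals[2, ])
  expect_equal(icr(m, c("I1", "I2")), (z1 + z2) / 2, tolerance = 1e-12)
  expect_equal(mean(icr(m, c("I1", "I2"))), 0, tolerance = 1e-10)

  # sample holding the max of every gene gets the max ICR
  set.seed(2)
  big <- matrix(runif(50 * 10), 50, 10,
                dimnames = list(sprintf("I%02d", 1:50), sprintf("s%02d", 1:10)))
  big[, 10] <- 2
  score <- icr(expression_matrix(big), rownames(big))
  expect_identical(names(which.max(score)), "s10")

  flat <- rbind(vals, FLAT = c(5, 5, 5))
  expect_warning(icr(expression_matrix(flat), rownames(flat)),
                 "zero-variance")
})

test_that("EMT is the Welch t contrast, mesenchymal minus epithelial", {
  vals <- matrix(c(5, 6, 7, 1, 2, 3), 6, 1,
                 dimnames = list(c("M1", "M2", "M3", "E1", "E2", "E3"), "s1"))
  m <- expression_matrix(vals)
  got <- emt(m, epithelial = c("E1", "E2", "E3"),
             mesenchymal = c("M1", "M2", "M3"))
  expect_equal(unname(got), 4 / sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)

  same <- toy_expr(rep(2, 4), c("M1", "M2", "E1", "E2"), "s1")
  expect_equal(unname(emt(same, c("E1", "E2"), c("M1", "M2"))), 0)
  expect_error(emt(m, "E1", c("M1", "M2")), ">= 2")
})

test_that("ssGSEA matches the direct-summation oracle and is rank-invariant", {
  genes <- c("A", "B", "C", "D", "E")
  x <- c(5, 4, 3, 2, 1)
  m <- toy_expr(x, genes, "s1")
  sets <- gene_set_collection(list(TOP = c("A", "B"), MID = c("B", "D")))
  for (tau in c(0, 0.25, 1)) {
    es <- ssgsea(m, sets, ssgsea_params(tau = tau, normalize = FALSE))
    for (nm in names(sets))
      expect_equal(es[nm, "s1"],
                   oracle_ssgsea_es(m[, "s1"], sets[[nm]], tau),
                   tolerance = 1e-12, label = sprintf("%s tau=%g", nm, tau))
  }

  # multi-sample with ties, against the oracle per sample
  set.seed(5)
  mm <- expression_matrix(matrix(round(runif(40), 1), 8, 5,
        dimnames = list(LETTERS[1:8], sprintf("s%d", 1:5))))
  set2 <- gene_set_collection(list(S = c("A", "C", "H")))
  es2 <- ssgsea(mm, set2, ssgsea_params(tau = 0.25, normalize = FALSE))
  for (j in 1:5)
    expect_equal(es2["S", j], oracle_ssgsea_es(mm[, j], set2$S, 0.25),
                 tolerance = 1e-12)

  # monotone transform of one sample leaves its scores unchanged
  mono <- mm
  mono[, 2] <- exp(mono[, 2])
  es_mono <- ssgsea(expression_matrix(mono), set2,
                    ssgsea_params(tau = 0.25, normalize = FALSE))
  expect_equal(es_mono["S", 2], es2["S", 2], tolerance = 1e-12)

  # degenerate set covering all genes is rejected; no overlap is skipped
  expect_error(ssgsea(m, gene_set_collection(list(ALL = genes))),
               "proper subset")
  expect_warning(
    es3 <- ssgsea(m, gene_set_collection(list(TOP = c("A", "B"),
                                              GONE = c("X", "Y")))),
    "no overlap")
  expect_identical(rownames(es3), "TOP")
})

test_that("scores are invariant to gene and sample ordering", {
  co <- test_cohort(seed = 13, n_samples = 50, n_lncrnas = 20,
                    n_true_modifiers = 5)
  panel <- co$truth$gene_id[co$truth$is_modifier]
  expr <- co$expression
  set.seed(3)
  gperm <- sample(nrow(expr)); sperm <- sample(ncol(expr))
  shuffled <- expression_matrix(expr[gperm, sperm])
  expect_equal(tisi(shuffled, panel)[colnames(expr)], tisi(expr, panel))
  expect_equal(icr(shuffled, panel)[colnames(expr)], icr(expr, panel))
})

test_that("TISI from true modifiers tracks latent infiltration on synthetic cohorts", {
  # population-level property, checked as a Monte-Carlo mean over 3 cohorts:
  # the sign-oriented modifier panel mean tracks the mean latent infiltration
  # of the targeted cell types
  rho <- vapply(c(17, 18, 19), function(seed) {
    co <- test_cohort(seed = seed)
    mods <- co$truth[co$truth$is_modifier, ]
    expr_signed <- co$expression[mods$gene_id, , drop = FALSE] * mods$sign
    panel_mean <- colMeans(expr_signed)
    latent_mean <- rowMeans(sapply(seq_len(nrow(mods)), function(i)
      co$latent_infiltration[, mods$target_cell_type[i]]))
    abs(cor(panel_mean, latent_mean, method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rho), 0.8)

  # immune ssGSEA score of the marker set rises with mean latent infiltration
  co <- test_cohort(seed = 17)
  es <- ssgsea(co$expression, co$marker_sets["IMMUNE"], ssgsea_params())
  overall <- rowMeans(co$latent_infiltration)
  expect_gt(cor(es["IMMUNE", ], overall, method = "spearman"), 0.5)
})
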