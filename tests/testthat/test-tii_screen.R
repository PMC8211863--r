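test_that("expression filter removes genes with zeros in >20% of samples, keeps boundary", {
  n <- 100
  m <- rbind(
    over = c(rep(0, 25), runif(75) + 0.1),   # 25% zeros: removed
    at   = c(rep(0, 20), runif(80) + 0.1),   # exactly 20%: kept
    none = runif(n) + 0.1                     # all positive: kept
  )
  colnames(m) <- sprintf("s%03d", 1:n)
  kept <- filter_expressed(expression_matrix(m), 0.20)
  expect_setequal(rownames(kept), c("at", "none"))
  expect_error(filter_expressed(expression_matrix(m[1, , drop = FALSE]), 0.2),
               "all genes filtered")
})

test_that("Pearson correlation and p match the closed form and a reference implementation", {
  expect_equal(pearson_with_p(1:4, 1:4)$pcc, 1)
  expect_lt(pearson_with_p(1:4, 1:4)$p_value, 1e-10)
  expect_equal(pearson_with_p(1:4, 4:1)$pcc, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  got <- pearson_with_p(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(got$pcc, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  # constant vector: degeneracy flag, never NaN
  d <- pearson_with_p(rep(2, 5), 1:5)
  expect_true(d$degenerate)
  expect_identical(c(d$pcc, d$p_value), c(0, 1))
})

test_that("Pearson p agrees with a permutation p on a small toy", {
  set.seed(21)
  x <- rnorm(8); y <- 0.8 * x + 0.5 * rnorm(8)
  p_t <- pearson_with_p(x, y)$p_value
  p_perm <- oracle_pearson_perm_p(x, y, n_perm = 1e5)
  expect_lt(abs(p_t - p_perm), 0.01)
})

test_that("step 1 passes planted modifiers and almost never nulls", {
  co <- test_cohort(seed = 7)
  parts <- split_cohort_expr(co)
  s1 <- step1_marker_correlation(parts$lnc, parts$markers, screen_params())
  mods <- co$truth$gene_id[co$truth$is_modifier]
  nulls <- co$truth$gene_id[!co$truth$is_modifier]
  expect_true(all(mods %in% s1$passed))
  expect_lt(mean(nulls %in% s1$passed), 0.01)

  # threshold of 1 admits only exact linear duplicates
  strict <- screen_params(pcc_threshold = 1)
  s1_strict <- step1_marker_correlation(parts$lnc, parts$markers, strict)
  expect_identical(s1_strict$passed, character(0))
  self <- step1_marker_correlation(parts$lnc[1:3, ], parts$lnc[1:3, ], strict)
  expect_setequal(self$passed, rownames(parts$lnc)[1:3])

  expect_error(step1_marker_correlation(
    parts$lnc, parts$markers[, character(0), drop = FALSE]), "shared")
})

test_that("step 2 links modifiers to their planted cell type and flags degenerates", {
  co <- test_cohort(seed = 7)
  parts <- split_cohort_expr(co)
  s2 <- step2_abundance_correlation(parts$lnc, co$abundance, screen_params())
  mods <- co$truth[co$truth$is_modifier, ]
  expect_true(all(mods$gene_id %in% s2$passed))
  hit <- vapply(seq_len(nrow(mods)), function(i)
    mods$target_cell_type[i] %in% s2$passed_cell_types[[mods$gene_id[i]]],
    logical(1))
  expect_true(mean(hit) >= 0.95)

  const <- parts$lnc
  const["LNC0001", ] <- 1
  s2c <- step2_abundance_correlation(const["LNC0001", , drop = FALSE],
                                     co$abundance, screen_params())
  expect_true(all(s2c$records$degenerate))
  expect_identical(s2c$passed, character(0))

  one_ct <- co$abundance[, 1, drop = FALSE]
  s2o <- step2_abundance_correlation(parts$lnc, one_ct, screen_params())
  expect_identical(unique(s2o$records$partner_id), colnames(co$abundance)[1])
})

test_that("quartile DE uses exact Wilcoxon where applicable", {
  # 4 vs 4, clean separation: exact two-sided p = 2/70
  wt <- tiilnc:::wilcox_rank_sum(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(wt$p_value, 2 / 70, tolerance = 1e-12)

  # identical expression in both groups -> p = 1; rank-matching lncRNA -> minimal p
  n <- 40
  ab <- matrix(seq(0, 1, length.out = n) / 1, n, 1,
               dimnames = list(sprintf("s%02d", 1:n), "CT01"))
  ab <- cbind(ab, 1 - ab); colnames(ab) <- c("CT01", "CT02")
  lnc <- rbind(flat = rep(3, n), track = seq_len(n) + 0)
  colnames(lnc) <- rownames(ab)
  de <- step3_quartile_de(expression_matrix(lnc), abundance_matrix(ab),
                          screen_params())
  flat <- de[de$lncrna_id == "flat" & de$cell_type == "CT01", ]
  expect_equal(flat$p_value, 1)
  track <- de[de$lncrna_id == "track" & de$cell_type == "CT01", ]
  expect_equal(track$p_value,
               stats::wilcox.test(31:40, 1:10, exact = TRUE)$p.value)
  expect_identical(track$direction, "up_in_high")
  expect_identical(c(track$n_high, track$n_low), c(10L, 10L))
})

test_that("the composed screen recovers planted modifiers and controls nulls", {
  co <- test_cohort(seed = 7)
  parts <- split_cohort_expr(co)
  res <- run_screen(parts$lnc, parts$markers, co$abundance, screen_params())
  truth_pos <- co$truth$gene_id[co$truth$is_modifier]
  tp <- sum(res$passed_lncrnas %in% truth_pos)
  expect_gte(tp / length(truth_pos), 0.90)                  # sensitivity
  expect_gte(tp / length(res$passed_lncrnas), 0.90)         # precision

  # step composition is recomputable from the evidence tables
  s3 <- res$evidence$step3
  de_pass <- unique(s3$lncrna_id[s3$pass])
  expect_true(all(res$passed_lncrnas %in% de_pass))
  summ <- screen_summary(res)
  expect_setequal(summ$lncrna_id[summ$passed], res$passed_lncrnas)
})

test_that("raising the PCC threshold never grows the passed set", {
  co <- test_cohort(seed = 9, n_samples = 150, n_lncrnas = 60,
                    n_true_modifiers = 10)
  parts <- split_cohort_expr(co)
  grid <- c(0.1, 0.2, 0.3, 0.45, 0.6)
  sets <- lapply(grid, function(thr)
    run_screen(parts$lnc, parts$markers, co$abundance,
               screen_params(pcc_threshold = thr))$passed_lncrnas)
  for (i in seq_len(length(grid) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  # lowering the p threshold never grows the set either
  p_grid <- c(0.05, 0.01, 0.001)
  psets <- lapply(p_grid, function(p)
    run_screen(parts$lnc, parts$markers, co$abundance,
               screen_params(p_threshold = p, de_p_threshold = p))$passed_lncrnas)
  for (i in seq_len(length(p_grid) - 1))
    expect_true(all(psets[[i + 1]] %in% psets[[i]]))
})

test_that("the screen is invariant to a consistent sample permutation", {
  co <- test_cohort(seed = 11, n_samples = 120, n_lncrnas = 40,
                    n_true_modifiers = 8)
  parts <- split_cohort_expr(co)
  base <- run_screen(parts$lnc, parts$markers, co$abundance, screen_params())
  set.seed(1)
  perm <- sample(colnames(parts$lnc))
  shuf <- run_screen(parts$lnc[, perm], parts$markers[, perm],
                     co$abundance[perm, ], screen_params())
  expect_setequal(shuf$passed_lncrnas, base$passed_lncrnas)
  expect_identical(shuf$linked_cell_type[sort(names(shuf$linked_cell_type))],
                   base$linked_cell_type[sort(names(base$linked_cell_type))])
})
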