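#' Simulation configuration for synthetic pan-cancer cohorts
#'
#' The generator plants a linear-Gaussian coupling between modifier lncRNAs
#' and latent per-cell-type infiltration, so the population Pearson
#' correlation between a modifier and its latent has the closed form
#' beta / sqrt(beta^2 + sigma^2). The defaults (beta = 0.6, sigma = 0.8)
#' give a population PCC of exactly 0.6, the operating point at which the
#' three-step screen is characterised.
#'
#' @param n_samples number of tumors in the cohort
#' @param n_cancer_types number of cancer-type labels (uniformly assigned)
#' @param n_lncrnas total lncRNAs simulated
#' @param n_true_modifiers how many lncRNAs are planted modifiers
#' @param n_marker_genes_per_cell_type immune marker genes per cell type
#' @param n_cell_types latent infiltrating immune cell populations
#' @param coupling_beta linear coupling of a modifier to its latent
#' @param noise_sd residual sd of every simulated gene
#' @param marker_coupling linear coupling of marker genes to their latent
#' @param concentration_coupling strength with which the Dirichlet
#'   concentration of a cell type increases in its latent
#' @param dirichlet_alpha0 baseline Dirichlet concentration
#' @param censor_rate target fraction of censored samples, in [0, 1)
#' @param hazard_coef log-hazard per unit of -TISI_true
#' @param base_hazard baseline exponential hazard (per day)
#' @param response_logit_coef ICI-response log-odds per sd of -TISI_true
#' @param response_rate target marginal ICI response rate
#' @param seed master seed; every random draw derives from it
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_samples = 500, n_cancer_types = 5, n_lncrnas = 200,
                       n_true_modifiers = 20, n_marker_genes_per_cell_type = 5,
                       n_cell_types = 5, coupling_beta = 0.6, noise_sd = 0.8,
                       marker_coupling = 1, concentration_coupling = 1,
                       dirichlet_alpha0 = 2, censor_rate = 0.3,
                       hazard_coef = 1, base_hazard = 1 / 1000,
                       response_logit_coef = 2, response_rate = 0.3,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_samples", "n_cancer_types", "n_lncrnas", "n_true_modifiers",
              "n_marker_genes_per_cell_type", "n_cell_types")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("config error: ", nm, " must be >= 1")
  if (cfg$n_true_modifiers > cfg$n_lncrnas)
    stop("config error: n_true_modifiers exceeds n_lncrnas")
  if (cfg$noise_sd <= 0) stop("config error: noise_sd must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("config error: censor_rate must lie in [0, 1)")
  if (cfg$response_rate <= 0 || cfg$response_rate >= 1)
    stop("config error: response_rate must lie in (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pan-cancer cohort with planted TII-lncRNAs
#'
#' Generative model, per sample s and cell type c:
#' * latent infiltration z[s, c] ~ Normal(0, 1) i.i.d.;
#' * cell fractions: Dirichlet draw with concentration
#'   alpha0 * exp(kappa * z[s, c]), so each cell type's fraction increases
#'   stochastically in its own latent;
#' * marker gene g of cell type c: a * z[s, c] + Normal(0, sigma);
#' * modifier lncRNA l with planted sign: sign * beta * z[s, c(l)] +
#'   Normal(0, sigma); null lncRNA: Normal(0, sqrt(beta^2 + sigma^2)) pure
#'   noise (variance matched to the modifiers so marginal distributions are
#'   indistinguishable);
#' * every gene is shifted to min 0, keeping the log2(x+1)-like non-negative
#'   convention while leaving all correlations untouched;
#' * TISI_true = per-sample mean of planted modifier expression; survival
#'   time ~ Exponential with log-hazard hazard_coef * (-TISI_true), with
#'   independent Uniform censoring calibrated to `censor_rate`.
#'
#' @param config a [sim_config()]
#' @return a `tii_cohort` list: `expression` (lncRNAs + markers, genes x
#'   samples), `abundance` (samples x cell types), `clinical`, `truth`
#'   (per-lncRNA flag, sign, target cell type), `latent_infiltration`,
#'   `marker_sets` (gene-set collection, one set per cell type plus the
#'   pooled IMMUNE set), `tisi_true` and the echoed config
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(derive_seed(cfg$seed, "cohort"))

  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  cell_types <- sprintf("CT%02d", seq_len(cfg$n_cell_types))

  z <- matrix(stats::rnorm(n * cfg$n_cell_types), n, cfg$n_cell_types,
              dimnames = list(samples, cell_types))

  # Dirichlet via independent gammas; concentration increases in the latent
  alpha <- cfg$dirichlet_alpha0 * exp(cfg$concentration_coupling * z)
  g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              n, cfg$n_cell_types, dimnames = dimnames(z))
  g[g == 0] <- .Machine$double.xmin  # guard against underflow at tiny shapes
  fractions <- g / rowSums(g)
  abundance <- abundance_matrix(fractions)

  # marker genes
  m_per <- cfg$n_marker_genes_per_cell_type
  marker_ids <- as.vector(vapply(cell_types, function(ct)
    sprintf("MRK_%s_%02d", ct, seq_len(m_per)), character(m_per)))
  marker_expr <- matrix(NA_real_, length(marker_ids), n,
                        dimnames = list(marker_ids, samples))
  for (ci in seq_along(cell_types)) {
    rows <- (ci - 1) * m_per + seq_len(m_per)
    eps <- matrix(stats::rnorm(m_per * n, sd = cfg$noise_sd), m_per, n)
    marker_expr[rows, ] <- cfg$marker_coupling *
      matrix(z[, ci], m_per, n, byrow = TRUE) + eps
  }

  # lncRNAs: first n_true_modifiers are planted modifiers
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncrnas))
  n_mod <- cfg$n_true_modifiers
  target <- sample(seq_len(cfg$n_cell_types), n_mod, replace = TRUE)
  sign_ <- sample(c(1, -1), n_mod, replace = TRUE)
  total_sd <- sqrt(cfg$coupling_beta^2 + cfg$noise_sd^2)
  lnc_expr <- matrix(NA_real_, cfg$n_lncrnas, n,
                     dimnames = list(lnc_ids, samples))
  for (i in seq_len(n_mod)) {
    lnc_expr[i, ] <- sign_[i] * cfg$coupling_beta * z[, target[i]] +
      stats::rnorm(n, sd = cfg$noise_sd)
  }
  if (n_mod < cfg$n_lncrnas) {
    idx <- (n_mod + 1):cfg$n_lncrnas
    lnc_expr[idx, ] <- matrix(stats::rnorm(length(idx) * n, sd = total_sd),
                              length(idx), n)
  }

  expr <- rbind(lnc_expr, marker_expr)
  expr <- expr - apply(expr, 1, min)  # shift each gene to min 0
  expr <- expression_matrix(expr)

  truth <- data.frame(
    gene_id = lnc_ids,
    is_modifier = seq_len(cfg$n_lncrnas) <= n_mod,
    sign = c(sign_, rep(NA_real_, cfg$n_lncrnas - n_mod)),
    target_cell_type = c(cell_types[target],
                         rep(NA_character_, cfg$n_lncrnas - n_mod)),
    stringsAsFactors = FALSE
  )

  tisi_true <- colMeans(expr[lnc_ids[seq_len(n_mod)], , drop = FALSE])

  # exponential survival with TISI-linked hazard + calibrated uniform censoring
  rate <- cfg$base_hazard * exp(cfg$hazard_coef * (-(tisi_true - mean(tisi_true))))
  t_event <- stats::rexp(n, rate = rate)
  if (cfg$censor_rate > 0) {
    u <- stats::runif(n)
    cens_frac <- function(cmax) mean(cmax * u < t_event) - cfg$censor_rate
    lo <- min(t_event) / 2; hi <- max(t_event) * 100
    cmax <- tryCatch(stats::uniroot(cens_frac, c(lo, hi))$root,
                     error = function(e) stats::quantile(t_event, 1 - cfg$censor_rate))
    t_cens <- cmax * u
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  clinical <- clinical_table(data.frame(
    sample_id = samples,
    cancer_type = sprintf("CA%02d", sample(seq_len(cfg$n_cancer_types), n,
                                           replace = TRUE)),
    time = time, event = event, stringsAsFactors = FALSE
  ))

  marker_sets <- split(marker_ids, rep(cell_types, each = m_per))[cell_types]
  marker_sets$IMMUNE <- marker_ids
  marker_sets <- gene_set_collection(marker_sets)

  structure(list(expression = expr, abundance = abundance,
                 clinical = clinical, truth = truth,
                 latent_infiltration = z, marker_sets = marker_sets,
                 tisi_true = tisi_true, config = cfg),
            class = "tii_cohort")
}

#' Simulate a cohort with immune-checkpoint-inhibitor response
#'
#' Extends [simulate_cohort()] with a binary response drawn as
#' Bernoulli(plogis(alpha + coef * std(-TISI_true))), where the coefficient
#' is per standard deviation of -TISI_true and the intercept alpha is solved
#' so that the marginal response rate matches `response_rate` (default 0.3).
#'
#' @inheritParams simulate_cohort
#' @return a `tii_cohort` whose clinical table gains a `response` column
#' @export
simulate_ici_cohort <- function(config) {
  cohort <- simulate_cohort(config)
  cfg <- cohort$config
  set.seed(derive_seed(cfg$seed, "ici-response"))
  s <- -cohort$tisi_true
  s <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
  f <- function(a) mean(stats::plogis(a + cfg$response_logit_coef * s)) -
    cfg$response_rate
  alpha <- stats::uniroot(f, c(-50, 50), extendInt = "yes")$root
  p <- stats::plogis(alpha + cfg$response_logit_coef * s)
  cohort$clinical$response <- stats::rbinom(length(p), 1, p)
  cohort
}

#' Simulate an expression matrix with planted sample clusters
#'
#' Spherical Gaussian clusters for validating consensus clustering: cluster
#' centers are placed on a scaled simplex so every pair of centers is
#' exactly `separation * noise_sd` apart in Euclidean distance; per-feature
#' noise is Normal(0, noise_sd). The matrix is shifted to min 0 per feature
#' to keep the expression-matrix convention.
#'
#' @param n_clusters number of planted clusters
#' @param n_per_cluster samples per cluster
#' @param n_features features (needs n_features >= n_clusters)
#' @param separation distance between cluster centers in noise-sd units
#' @param noise_sd within-cluster sd
#' @param seed integer seed
#' @return list with `expression` (features x samples) and integer `labels`
#' @export
simulate_clustered_expression <- function(n_clusters = 3, n_per_cluster = 50,
                                          n_features = 20, separation = 6,
                                          noise_sd = 1, seed = 1) {
  stopifnot(n_features >= n_clusters, n_clusters >= 1)
  set.seed(derive_seed(seed, "clusters"))
  n <- n_clusters * n_per_cluster
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  centers <- matrix(0, n_clusters, n_features)
  for (k in seq_len(n_clusters))
    centers[k, k] <- separation * noise_sd / sqrt(2)
  x <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
  expr <- t(x)
  dimnames(expr) <- list(sprintf("F%03d", seq_len(n_features)),
                         sprintf("S%04d", seq_len(n)))
  expr <- expr - apply(expr, 1, min)
  list(expression = expression_matrix(expr), labels = labels)
}

#' Write a synthetic cohort's tables to an output directory
#'
#' Writes expression.tsv, abundance.tsv, clinical.tsv, truth.tsv and
#' markers.gmt, each TSV carrying a provenance header comment.
#'
#' @param cohort a `tii_cohort`
#' @param dir output directory (created if needed)
#' @return invisible character vector of written paths
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tii_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, c("expression.tsv", "abundance.tsv", "clinical.tsv",
                        "truth.tsv", "markers.gmt"))
  params <- paste0("seed=", cohort$config$seed)
  write_matrix_tsv(cohort$expression, p[1], id_col = "gene_id", params = params)
  write_matrix_tsv(cohort$abundance, p[2], id_col = "sample_id", params = params)
  write_table_tsv(cohort$clinical, p[3], params = params)
  write_table_tsv(cohort$truth, p[4], params = params)
  write_gmt(cohort$marker_sets, p[5])
  invisible(p)
}
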