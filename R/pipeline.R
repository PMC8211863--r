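#' End-to-end pipeline configuration
#'
#' Collects the per-stage parameter objects and the master seed. Every
#' stochastic stage derives its stream from the one seed, so a config fully
#' determines all outputs.
#'
#' @param sim [sim_config()] for the synthetic cohort
#' @param screen [screen_params()]
#' @param consensus [consensus_params()] (its seed is overridden by `seed`)
#' @param ssgsea [ssgsea_params()]
#' @param ici_sim optional [sim_config()] for the ICI-response cohort; NULL
#'   skips the response-evaluation stage
#' @param seed master seed applied to every stage
#' @return validated `pipeline_config` list
#' @export
pipeline_config <- function(sim = sim_config(), screen = screen_params(),
                            consensus = consensus_params(),
                            ssgsea = ssgsea_params(),
                            ici_sim = sim_config(n_samples = 300, seed = 2),
                            seed = 1) {
  stopifnot(inherits(sim, "sim_config"), inherits(screen, "screen_params"),
            inherits(consensus, "consensus_params"),
            inherits(ssgsea, "ssgsea_params"))
  if (!is.null(ici_sim)) stopifnot(inherits(ici_sim, "sim_config"))
  sim$seed <- derive_seed(seed, "stage-simulate")
  consensus$seed <- derive_seed(seed, "stage-cluster")
  if (!is.null(ici_sim)) ici_sim$seed <- derive_seed(seed, "stage-ici")
  structure(list(sim = sim, screen = screen, consensus = consensus,
                 ssgsea = ssgsea, ici_sim = ici_sim, seed = seed),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Stages, in order: simulate -> screen -> score -> cluster -> survival ->
#' ici-eval. Every stage's tables are written under `out_dir` and listed in
#' a JSON manifest together with the parameters and seed; re-running with
#' an identical config reproduces identical outputs. A stage failure halts
#' the run with the stage name, leaving earlier outputs on disk.
#'
#' @param config [pipeline_config()]
#' @param out_dir output directory
#' @return invisible list with the in-memory stage results and the manifest
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "tiilnc", version = tiilnc_version(),
                   seed = config$seed, stages = list())
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  record <- function(name, files, info = list()) {
    manifest$stages[[name]] <<- c(list(files = I(basename(files))), info)
  }

  ## 1. simulate
  cohort <- stage("simulate", function() simulate_cohort(config$sim))
  sim_dir <- file.path(out_dir, "cohort")
  files <- write_cohort(cohort, sim_dir)
  record("simulate", files, list(n_samples = config$sim$n_samples,
                                 n_lncrnas = config$sim$n_lncrnas))

  ## 2. screen
  lnc_ids <- cohort$truth$gene_id
  marker_ids <- setdiff(rownames(cohort$expression), lnc_ids)
  screen_res <- stage("screen", function() run_screen(
    cohort$expression[lnc_ids, , drop = FALSE],
    cohort$expression[marker_ids, , drop = FALSE],
    cohort$abundance, config$screen))
  f <- file.path(out_dir, "screen_result.tsv")
  write_table_tsv(screen_summary(screen_res), f,
                  params = sprintf("pcc>=%g p<%g", config$screen$pcc_threshold,
                                   config$screen$p_threshold))
  record("screen", f, list(n_passed = length(screen_res$passed_lncrnas)))
  panel <- screen_res$passed_lncrnas
  if (!length(panel)) stop("pipeline stage 'screen' passed no lncRNAs")

  ## 3. score
  scores <- stage("score", function() score_samples(
    cohort$expression, panel, gene_sets = cohort$marker_sets["IMMUNE"],
    ssgsea_opts = config$ssgsea))
  f <- file.path(out_dir, "scores.tsv")
  write_table_tsv(scores, f)
  record("score", f, list(scores = setdiff(names(scores), "sample_id")))

  ## 4. cluster
  cl <- stage("cluster", function() consensus_cluster(
    cohort$expression[panel, , drop = FALSE], config$consensus))
  k <- cl$selected_k
  assign_df <- data.frame(sample_id = colnames(cohort$expression),
                          cluster = cl$assignments[[as.character(k)]])
  enr <- composition_enrichment(assign_df$cluster,
                                cohort$clinical$cancer_type)
  ksel <- data.frame(k = cl$k_range, cdf_area = unname(cl$cdf_area),
                     delta_area = unname(cl$delta_area),
                     selected = cl$k_range == k)
  f <- file.path(out_dir, c("assignments.tsv", "enrichment.tsv",
                            "kselect.tsv"))
  write_table_tsv(assign_df, f[1], params = sprintf("k=%d", k))
  write_table_tsv(enr, f[2])
  write_table_tsv(ksel, f[3])
  record("cluster", f, list(selected_k = k))

  ## 5. survival: TISI median split, log-rank + univariate Cox
  surv <- stage("survival", function() {
    grp <- stratify_by_median(scores$tisi)
    lr <- km_logrank(cohort$clinical$time, cohort$clinical$event, grp)
    cx <- cox_fit(cohort$clinical$time, cohort$clinical$event,
                  data.frame(tisi = scores$tisi))
    list(logrank = lr, cox = cx, group = grp)
  })
  surv_df <- data.frame(
    analysis = c("logrank_tisi_median", "cox_tisi"),
    statistic = c(surv$logrank$chi2, surv$cox$table$z[1]),
    hr = c(NA, surv$cox$table$hr[1]),
    ci_low = c(NA, surv$cox$table$ci_low[1]),
    ci_high = c(NA, surv$cox$table$ci_high[1]),
    p = c(surv$logrank$p, surv$cox$table$p[1]))
  f <- file.path(out_dir, "survival.tsv")
  write_table_tsv(surv_df, f)
  record("survival", f, list(cox_hr = surv$cox$table$hr[1]))

  ## 6. ici-eval: AUC of -TISI for response on an independent ICI cohort
  results <- list(cohort = cohort, screen = screen_res, scores = scores,
                  clustering = cl, enrichment = enr, survival = surv)
  if (!is.null(config$ici_sim)) {
    ici <- stage("ici-eval", function() {
      ic <- simulate_ici_cohort(config$ici_sim)
      sc <- tisi(ic$expression, panel[panel %in% rownames(ic$expression)])
      roc <- roc_auc(-sc, ic$clinical$response)
      list(cohort = ic, roc = roc)
    })
    f <- file.path(out_dir, "ici_auc.tsv")
    write_table_tsv(data.frame(score = "neg_tisi", auc = ici$roc$auc), f)
    record("ici-eval", f, list(auc = ici$roc$auc))
    results$ici <- ici
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
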