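#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival curves per group and the standard log-rank
#' chi-square on g - 1 degrees of freedom. Groups with zero events are
#' allowed (with a warning); identical groups give chi2 = 0, p = 1.
#'
#' @param times non-negative survival times
#' @param events event indicators (1 = death)
#' @param groups group labels (>= 2 distinct)
#' @return list: `curves` (per-group data.frames of time, n_risk, n_event,
#'   n_censor, surv), `chi2`, `df`, `p`
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  ev_per <- tapply(events, groups, sum)
  if (any(ev_per == 0))
    warning("group(s) with zero events: ",
            paste(names(ev_per)[ev_per == 0], collapse = ", "))
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata_id <- rep(names(fit$strata), fit$strata)
  curves <- lapply(levels(groups), function(g) {
    i <- strata_id == paste0("groups=", g)
    data.frame(time = fit$time[i], n_risk = fit$n.risk[i],
               n_event = fit$n.event[i], n_censor = fit$n.censor[i],
               surv = fit$surv[i])
  })
  names(curves) <- levels(groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  chi2 <- unname(sd$chisq)
  list(curves = curves, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Maximum partial likelihood with Efron tie handling (the standard
#' default); Wald confidence intervals and p-values per covariate. The
#' score test statistic at beta = 0 is returned as well: on a single binary
#' covariate without ties it equals the log-rank chi-square.
#'
#' @param times,events survival outcome
#' @param covariates data.frame or matrix of covariates (full rank required)
#' @param ties tie-handling method, default "efron"
#' @return a `cox_result` list: `table` (term, log_hr, hr, se, z, p,
#'   ci_low, ci_high), `n`, `n_events`, `score_chi2`, `converged`,
#'   `separation` (monotone-likelihood flag)
#' @export
cox_fit <- function(times, events, covariates, ties = "efron") {
  X <- as.data.frame(covariates)
  mm <- stats::model.matrix(~ ., data = X)
  if (qr(mm)$rank < ncol(mm))
    stop("covariate matrix is rank deficient (collinear columns)")
  if (sum(events) < 1) stop("need at least one event")
  dat <- cbind(data.frame(.time = times, .event = events), X)
  f <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(X)), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = dat, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  tab <- data.frame(term = rownames(co), log_hr = co[, "coef"],
                    hr = exp(co[, "coef"]), se = co[, "se(coef)"],
                    z = co[, "z"], p = co[, "Pr(>|z|)"],
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n = fit$n, n_events = fit$nevent,
                 score_chi2 = unname(fit$score),
                 converged = fit$iter < 100, separation = separation,
                 fit = fit),
            class = "cox_result")
}

#' Random-effects meta-analysis of log hazard ratios
#'
#' DerSimonian-Laird pooling: fixed weights 1/se^2 give the heterogeneity
#' statistic Q; tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)));
#' cohorts are re-weighted by 1/(se^2 + tau^2). A single cohort passes
#' through with tau^2 = 0 and a warning.
#'
#' @param log_hr per-cohort log hazard ratios
#' @param se per-cohort standard errors (> 0)
#' @return list: `pooled_log_hr`, `se`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `tau2`, `Q`, `I2`, `k`, `cohorts` (input echo)
#' @export
meta_random_effects <- function(log_hr, se) {
  stopifnot(length(log_hr) == length(se))
  if (any(!is.finite(log_hr)) || any(!is.finite(se)) || any(se <= 0))
    stop("log_hr and se must be finite with se > 0")
  k <- length(log_hr)
  if (k < 2) {
    warning("single cohort: passthrough with tau2 = 0")
    return(list(pooled_log_hr = log_hr, se = se, hr = exp(log_hr),
                ci_low = exp(log_hr - 1.96 * se),
                ci_high = exp(log_hr + 1.96 * se),
                p = 2 * stats::pnorm(abs(log_hr / se), lower.tail = FALSE),
                tau2 = 0, Q = 0, I2 = 0, k = 1,
                cohorts = data.frame(log_hr = log_hr, se = se)))
  }
  fit <- metafor::rma.uni(yi = log_hr, sei = se, method = "DL")
  b <- as.numeric(fit$b)
  list(pooled_log_hr = b, se = fit$se, hr = exp(b),
       ci_low = exp(fit$ci.lb), ci_high = exp(fit$ci.ub),
       p = fit$pval, tau2 = fit$tau2, Q = fit$QE, I2 = fit$I2, k = k,
       cohorts = data.frame(log_hr = log_hr, se = se))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique score values (a sample is called
#' positive when its score is >= the threshold); the AUC is computed from
#' the rank formulation, so ties contribute one half:
#' AUC = P(score+ > score-) + 0.5 P(score+ = score-), identically the
#' Mann-Whitney U statistic divided by n1 * n0.
#'
#' @param scores numeric predictor (higher = more likely positive)
#' @param labels binary labels, both classes present
#' @return list: `thresholds`, `tpr`, `fpr`, `auc`
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be coded 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

#' Split samples into high/low groups at a score quantile
#'
#' high = score strictly above the cut, low = score at or below it (ties go
#' low, deterministically). The default cut is the median.
#'
#' @param scores numeric vector, length >= 2, non-constant
#' @param prob quantile of the cut, default 0.5
#' @return factor with levels `low`, `high`
#' @export
stratify_by_median <- function(scores, prob = 0.5) {
  if (length(scores) < 2) stop("need at least 2 samples")
  cut <- stats::quantile(scores, prob, names = FALSE)
  g <- ifelse(scores > cut, "high", "low")
  if (length(unique(g)) < 2) stop("degenerate split: constant scores")
  factor(g, levels = c("low", "high"))
}
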