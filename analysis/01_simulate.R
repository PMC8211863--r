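#!/usr/bin/env Rscript
# Stage 1: generate the synthetic pan-cancer cohort with planted TII-lncRNAs
# and a companion immunotherapy (ICI) cohort, and persist every table.
#
# The cohort mirrors the study conditions the screen is characterised at:
# 500 tumors, 200 lncRNAs of which 20 are planted infiltration modifiers at
# population PCC 0.6, 5 latent immune cell types with 5 marker genes each.

suppressPackageStartupMessages(library(tiilnc))

seed <- 7
cohort <- simulate_cohort(sim_config(seed = seed))
write_cohort(cohort, "results/cohort")

ici <- simulate_ici_cohort(sim_config(n_samples = 300, hazard_coef = 1,
                                      response_logit_coef = 2,
                                      seed = seed + 1))
write_cohort(ici, "results/ici_cohort")

mods <- cohort$truth[cohort$truth$is_modifier, ]
message(sprintf(
  "cohort: %d genes x %d samples; %d planted modifiers (%d +, %d -); %.0f%% censored",
  nrow(cohort$expression), ncol(cohort$expression), nrow(mods),
  sum(mods$sign > 0), sum(mods$sign < 0),
  100 * mean(cohort$clinical$event == 0)))
message(sprintf("ici cohort: %d samples, response rate %.2f",
                ncol(ici$expression), mean(ici$clinical$response)))
message("written: results/cohort, results/ici_cohort")
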