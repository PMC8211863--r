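#!/usr/bin/env Rscript
# Stage 6: immunotherapy-response prediction — ROC of -TISI against the
# binary ICI response on the held-out ICI cohort (responders are expected
# at low TISI, so the predictor is the negated score).

suppressPackageStartupMessages(library(tiilnc))

expr <- read_expression("results/ici_cohort/expression.tsv")
clinical <- read_clinical("results/ici_cohort/clinical.tsv")
panel <- readLines("results/tii_panel.txt")
panel <- panel[panel %in% rownames(expr)]

scores <- tisi(expr, panel)
roc <- roc_auc(-scores, clinical$response)
write_table_tsv(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                           fpr = roc$fpr),
                "results/roc.tsv", params = sprintf("auc=%.4f", roc$auc))

grp <- stratify_by_median(scores)
resp_by <- tapply(clinical$response, grp, mean)
message(sprintf("AUC of -TISI for ICI response: %.3f (n = %d, %d responders)",
                roc$auc, length(scores), sum(clinical$response)))
message(sprintf("response rate: %.2f in TISI-low vs %.2f in TISI-high",
                resp_by["low"], resp_by["high"]))
message("written: results/roc.tsv")
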