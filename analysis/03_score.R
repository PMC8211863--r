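#!/usr/bin/env Rscript
# Stage 3: per-sample immune indices on the screened panel.
#
# TISI is the mean expression of the screened lncRNA panel; the IMMUNE
# marker geneset is scored by ssGSEA as the cohort's immune score. (CYT,
# ICR and EMT need their dedicated gene lists, which a synthetic cohort
# does not plant; on real data they are supplied through the same GMT
# interface with the reserved set names ICR / EPITHELIAL / MESENCHYMAL.)

suppressPackageStartupMessages(library(tiilnc))

expr <- read_expression("results/cohort/expression.tsv")
panel <- readLines("results/tii_panel.txt")
markers <- read_gmt("results/cohort/markers.gmt")

scores <- score_samples(expr, panel, gene_sets = markers["IMMUNE"])
write_table_tsv(scores, "results/scores.tsv",
                params = sprintf("panel=%d lncRNAs", length(panel)))

rho <- cor(scores$tisi, scores$es_IMMUNE, method = "spearman")
message(sprintf("scored %d samples; Spearman(TISI, immune ssGSEA) = %.2f",
                nrow(scores), rho))
message("written: results/scores.tsv")
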