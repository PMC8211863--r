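# tiilnc

Systems-immunology workflow for nominating **lncRNA modifiers of
tumor-infiltrating immune cells (TII-lncRNAs)** from bulk expression data,
and for characterising the tumor immune microenvironment downstream of the
screen: per-sample immune indices, consensus subtypes, survival and
immunotherapy-response statistics. It is written for computational
immuno-oncologists who have a gene × sample expression matrix, immune
marker gene sets, and per-sample immune-cell fractions (e.g. CIBERSORT
output, which is consumed as input — never recomputed), and want a tested,
reproducible implementation of the whole chain.

## What it computes

**The screen.** After removing lncRNAs with no expression in more than 20%
of samples, a lncRNA is nominated as a TII-lncRNA when all three hold:

1. it co-expresses with at least one immune marker gene
   (|*r*| ≥ 0.3, *P* < 0.05; two-sided *t* transform
   *t* = *r*·√((n−2)/(1−r²)));
2. it correlates with at least one immune cell type's abundance at the
   same thresholds;
3. it is differentially expressed (two-sided Wilcoxon, *P* < 0.05) between
   the top- and bottom-quartile infiltration groups of the *same* cell
   type.

**The indices.** TISI (mean panel expression; high = immune-silent
phenotype), CYT (geometric mean of GZMA and PRF1 on the linear scale), ICR
(mean cohort z-score of a 20-gene rejection signature), EMT (per-sample
Welch *t*, mesenchymal − epithelial), and Barbie-style ssGSEA
(rank-weighted running sum, τ = 0.25) for arbitrary gene sets including
stromal/immune scores.

**Subtypes.** Consensus K-means (100 × 80% subsamples, Euclidean, 10
restarts) with CDF delta-area k-selection, hypergeometric cancer-type
composition enrichment ES = (n_tc/n_c)/(n_t/N), and subsample robustness
(ARI against the full-data partition).

**Outcomes.** Kaplan–Meier/log-rank, Cox proportional hazards (Efron
ties), DerSimonian–Laird random-effects pooling of log hazard ratios
across cohorts, and ROC/AUC (rank-form, ties count one half) for ICI
response, with −TISI as the response predictor.

**Synthetic cohorts.** `simulate_cohort()` plants modifier lncRNAs with
linear-Gaussian coupling to latent per-cell-type infiltration — the
population lncRNA–latent correlation is β/√(β²+σ²), exactly 0.6 at the
defaults — plus Dirichlet cell fractions, TISI-linked exponential
survival, and TISI-linked Bernoulli ICI response, returning full ground
truth for recovery testing.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
it end to end reproduces a complete study on a synthetic cohort:

```sh
Rscript analysis/01_simulate.R    # cohort with planted ground truth
Rscript analysis/02_screen.R     # three-step TII-lncRNA screen
Rscript analysis/03_score.R      # TISI + ssGSEA immune score
Rscript analysis/04_cluster.R    # consensus subtypes + enrichment
Rscript analysis/05_survival.R   # KM/log-rank, Cox, HR meta-analysis
Rscript analysis/06_ici_response.R  # ROC for ICI response
```

Output of the screen and outcome stages on the default cohort (500
tumors, 200 lncRNAs, 20 planted modifiers at population correlation 0.6):

```
stage survivors: input=200, expressed=200, step1=20, step2=20, step3=20
screen recovery: sensitivity 1.00, precision 1.00

log-rank (TISI median split): chi2 = 11.7, p = 0.000634
Cox (per TISI sd): HR = 0.76 [0.68, 0.85], p = 9.8e-07
meta-analysis over 4 ICI cohorts: pooled HR = 0.69 [0.61, 0.79], tau2 = 0.011

AUC of -TISI for ICI response: 0.818 (n = 300, 91 responders)
response rate: 0.50 in TISI-low vs 0.11 in TISI-high
```

Reading these numbers: the screen recovered exactly the 20 planted
modifiers and nothing else; the TISI median split separates survival
(here the generator links *low* TISI to higher hazard, so the Cox HR per
TISI sd is below 1); pooling the per-cohort TISI hazard ratios over four
simulated ICI cohorts gives a pooled HR of 0.69 with negligible
between-cohort heterogeneity; and −TISI predicts the planted ICI response
at AUC 0.82 in a held-out cohort. All tables land under `results/` as TSV
with provenance header comments.

The same chain is available as one call — `run_pipeline(pipeline_config(seed = 1), "out/")` —
which writes every stage table plus a JSON manifest and is byte-reproducible
for a fixed config.

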