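# tmeprofiler

Immune-infiltrate profiling of the tumor microenvironment (TME) from bulk
and single-cell transcriptomes, built as a single tested pipeline. The
motivating setting is intrahepatic cholangiocarcinoma (ICC), where the
abundance and the *activity* of infiltrating immune cells — B cells, T
cells, NK cells, macrophages — shape prognosis, but every stage is generic
over a gene-by-sample expression table, a signature matrix, gene-set
collections, a clinical table, and a gene-by-cell count matrix.

The pipeline covers, end to end:

1. **Deconvolution** — relative immune cell-type fractions per bulk sample
   by nonnegative least squares against an LM22-style signature matrix,
   with per-sample permutation p-values, Wilcoxon group comparisons and
   abundance ranking.
2. **Activity scoring** — single-sample gene-set enrichment (ssGSEA) with
   the rank-weighted running-sum statistic, ESTIMATE-style
   Stromal/Immune/combined scores, and a composite per-sample
   immunoactivity (mean of z-scored set scores).
3. **Immunoactivity grouping** — exact optimal 1-D k-means (dynamic
   programming over sorted scores, minimizing the within-group sum of
   squared differences) into low / moderate / high groups.
4. **Slope change Δk** — per-state ordinary least squares of activity on
   abundance, `y = kx + b`, with `Δk = k_tumor − k_control`, a bootstrap
   confidence interval, and an enhanced / weakened / unchanged call:
   positive Δk means a cell type gains more activity per unit abundance in
   tumor than in control tissue.
5. **Differential expression and co-expression modules** — median-of-ratios
   normalization with Welch tests, PCA cluster checks (PC1–3 cumulative
   variance ≥ 75 %), and a compact signed-WGCNA workflow: soft power by
   scale-free fit, signed adjacency `((1+cor)/2)^β`, topological overlap,
   average-linkage tree cut, module eigengenes and kME ≥ 0.75 assignment,
   module–trait correlation.
6. **Survival** — Cox proportional hazards (Breslow ties), Kaplan–Meier +
   log-rank, and a cumulative/dynamic time-dependent ROC at a fixed horizon.
7. **Single cells** — sequential QC (gene detected in ≥ 100 cells, ≥ 300
   then ≥ 500 features per cell, ≤ 5 % mitochondrial reads), LogNormalize
   (scale factor 10 000), top-2000 HVG selection, PCA embedding, SNN
   (Jaccard) graph clustering, marker-score annotation, one-vs-rest
   cluster markers.
8. **Phenotype linkage** — Scissor-style selection: each cell's Pearson
   correlation with the bulk samples becomes a covariate of a Cox model
   for bulk survival, penalized by an L1 term plus a cell-graph Laplacian
   smoother, solved by proximal gradient descent. Cells with positive
   coefficients are poor-survival-associated ("plus"), negative are
   "minus", exact zeros are background; subpopulations are named
   type + group + sign (e.g. `BLp` = B cells, low-immunoactivity group,
   poor survival) and their marker signatures intersected with the
   co-expression module genes.
9. **Synthetic data** — generators with planted truth for every stage:
   Dirichlet mixtures of signature profiles with survival tied to one
   fraction, two-state slope pairs, negative-binomial single cells with a
   planted phenotype-linked subpopulation and engineered QC failures, and
   latent-factor co-expression blocks.

## Worked example

```r
library(tmeprofiler)

# a synthetic 40-sample cohort mixed from 6 cell-type signatures
b  <- generate_bulk_cohort(40, 200, 6, noise_sd = 0.1, seed = 3)
fr <- estimate_fractions(b$expr, b$truth$signature, n_perm = 20, seed = 1)
mean(sapply(1:40, function(i) cor(fr$fractions[i,], b$truth$fractions[i,])))
#> [1] 0.9974074          # estimated vs planted fractions, per-sample r

# activity scores, composite immunoactivity, optimal 3-group partition
sets <- gene_set_collection(setNames(b$truth$marker_genes,
                                     colnames(b$truth$signature)))
act  <- ssgsea_score(b$expr, sets)
comp <- composite_immunoactivity(act, colnames(b$truth$signature)[1:3])
partition_by_activity(comp)
#> ImmunoGroups: low=17 moderate=14 high=9 (wss=1.113)

# planted slope change 0.8 - 0.2 = 0.6, recovered with a bootstrap CI
ts <- generate_two_state(k_control = 0.2, k_tumor = 0.8, sigma = 0.05,
                         seed = 5)
ft <- fit_state_regression(ts$x[ts$state == "tumor"],
                           ts$y[ts$state == "tumor"], "tumor")
fc <- fit_state_regression(ts$x[ts$state == "control"],
                           ts$y[ts$state == "control"], "control")
delta_k(ft, fc, boot_reps = 500, seed = 2)
#> DeltaK: 0.5977 [0.4948, 0.6883] -> enhanced
```

The numbers read: deconvolution recovers the planted mixing fractions
almost exactly at 10 % multiplicative noise; the cohort splits into
17/14/9 low/moderate/high immunoactivity samples at the optimal
within-group sum of squares 1.11; and the planted tumor-vs-control slope
difference of 0.6 is estimated as 0.598 with a 95 % bootstrap interval
excluding zero, hence the "enhanced" call.

`run_pipeline(seed)` composes all nine stages on one simulated cohort —
from mixtures to the table of subpopulation signature genes intersected
with module genes — deterministically for a given seed.

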