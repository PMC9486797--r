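# ndmi — leukocyte-resolved blood methylation markers of glucocorticoid exposure

Whole-blood DNA methylation carries a readable record of glucocorticoid
(dexamethasone) exposure, concentrated in neutrophils. Because a blood
sample's beta value at a CpG is approximately the cell-fraction-weighted
average of cell-specific values, three pieces of machinery together make
that record usable as a pharmacodynamic marker:

* **Deconvolution** — estimate the six major leukocyte fractions
  (CD4 T, CD8 T, B, NK, monocytes, neutrophils) from whole-blood betas by
  non-negative least squares against a reference panel, `Y ≈ M w`,
  `w ≥ 0`, `Σw = 1`, plus the neutrophil/lymphocyte, CD4/CD8 and
  lymphocyte/monocyte ratios and absolute counts.
* **Cell-specific screening** — per CpG, an exposure EWAS filter
  (Welch t, `p < 0.05` and `|Δβ| ≥ 0.10`), then the no-intercept
  interaction model `y = Σ_k w_k a_k + Σ_k (x·w_k) b_k + ε` whose
  exposure-by-fraction coefficients localise differential methylation to
  a cell type; loci are partitioned into cell-specific and
  non-cell-specific sets with BH-FDR control and a coefficient-homogeneity
  test.
* **A sparse exposure index** — an elastic-net logistic classifier over
  CpG betas; its linear predictor `score = β0 + Σ βi·xi` transforms to
  `P(exposed) = 1 / (1 + e^(-score))`, the neutrophil-CpG version being a
  neutrophil dexamethasone methylation index (NDMI).

A generative simulator ties it together: beta-distributed cell-specific
methylomes (method-of-moments shapes from a reference panel),
Dirichlet(α0) cell fractions, exposure shifts injected into designated
cells, and convex mixing into whole blood — with ground truth retained,
so deconvolution accuracy, screen recovery, classifier performance and
statistical power are all measurable. No external or controlled-access
data are needed; the bundled reference panel is synthetic and labelled
as such.

## Worked example

```r
library(ndmi)

panel <- default_panel()                      # 500 synthetic CpGs, 6 cell types
cfg <- simulation_config(n0 = 76, n1 = 59,    # unexposed / exposed
                         alpha0 = 18, neutrophil_mean_fraction = 0.6,
                         seed = 20220920)
cohort <- generate_cohort(cfg, panel)         # default: hypomethylation at
                                              # the 28 index CpGs in neutrophils

# deconvolve and check against the simulated truth
W <- estimate_fractions(cohort$betas, panel_matrix(panel))$fractions
mean(abs(W - cohort$true_fractions))
#> [1] 0.005759827

# train the index on half the cohort, score the held-out half
idx <- panel_index_cpgs(panel)
ids <- colnames(cohort$betas)
train <- ids[c(1:38, 77:106)]; test <- setdiff(ids, train)
m <- fit_elastic_net(t(cohort$betas[idx, train]), cohort$labels[train],
                     seed = 1, family = "neutrophil_cpg")
sc <- ndmi_score(m, t(cohort$betas[idx, test]))
roc_auc(sc, cohort$labels[test])$auc
#> [1] 1
head(exposure_probability(sc), 3)
#>      ctrl039      ctrl040      ctrl041
#> 1.748637e-06 1.280206e-08 8.551839e-05
```

The index separates held-out exposed from unexposed samples cleanly under the simulator's conditions (held-out AUC 1 in this
cohort; ~0.99 on average across replicates); the scored probabilities
are each sample's modelled probability of current exposure — near zero
for these three unexposed controls. The numbered scripts under `analysis/` walk through the full
sequence — published-table reconstruction, cohort simulation,
deconvolution benchmark, cell-specific screen, index training and
evaluation, and the power surface — writing their tables under
`results/`.

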