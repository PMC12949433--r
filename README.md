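# hubnetreg

Network-guided penalized regression for high-dimensional proteomics (and
other omics) data: estimate the protein co-dependence network, keep its hub
proteins and the clinical confounders unpenalized, and let an adaptive lasso
select among the remaining features.

## The problem and the model

Given an abundance matrix `X` (n samples × p proteins), a low-dimensional
confounder matrix `Z`, and a continuous outcome `y`, the package fits the
two-stage estimator:

1. **Network stage.** A sparse Gaussian graphical model is estimated by the
   graphical lasso,

   `Θ̂ = argmax { log det Θ − tr(Σ̂Θ) − λ Σ_{j≠k} |θ_jk| }`,

   with λ tuned by the extended BIC
   `−2ℓ(Θ̂) + E log n + 4γE log p`. Partial correlations
   `ρ̂_jk = −θ̂_jk/√(θ̂_jj θ̂_kk)` define the network; each protein is
   scored by degree centrality `φ̂_k = Σ_j |ρ̂_jk|` and the top
   `h = min(⌊pδ⌋, τ)` proteins, `τ = ⌊(p+20)/16⌋`, are declared hubs.

2. **Regression stage.** With `U = (1, Z, hubs)` and `N` the non-hubs, the
   fit minimizes

   `‖y − Uα − Nβ‖² + λ_n Σ_j w_j |β_j|`, `w_j = |β̃_j|^(−ν)`,

   so hubs and confounders are never shrunk while non-hubs face an adaptive
   lasso whose weights come from a perturbed elastic-net initializer.
   `(ν, λ_n)` are chosen jointly by 5-fold cross-validation.

Baselines (adaptive lasso, lasso, elastic net, ridge — all penalizing every
non-intercept term uniformly), a synthetic-data generator with a
hub-clique/autoregressive correlation design, and evaluation metrics (RMSE
against the regression surface, calibration slope, F1, Matthews
correlation) are included for benchmarking. See the vignette
(`vignettes/network-guided-regression.Rmd`) for the model's assumptions,
tuning defaults and their rationale.

## Worked example

```r
library(hubnetreg)

d <- sim_data(sim_scenario("II", "strong", seed = 1))   # n=100, p=60
fit <- hubnetreg(d$x_train, d$z_train, d$y_train, delta = 0.06, seed = 1)
fit
#> Network-guided penalized regression
#>
#>   n = 100 samples, p = 60 features, 3 confounder(s)
#>   network: 553 edges (lambda = 0.02041 by eBIC, gamma = 0)
#>   hubs (h = 3, delta = 0.06): P1, P5, P4
#>   selected non-hubs: 7 of 57 (nu = 2, lambda = 27.29)

evaluate_fit(fit, d)
#> RMSE 0.578 | CSL 1.003 | F1 1.000 | MCC 1.000 | TP 13 FP 0 TN 50 FN 0

round(coef(fit, "hub"), 3)
#>    P1    P5    P4
#> 4.798 4.068 2.278
```

The three hubs land on true signal proteins (the simulated hub clique
carries coefficients of 3.5); all 13 truly active candidates and no nulls
are selected (F1 = 1), predictions deviate from the true regression surface
by 0.58 on average (against an outcome standard deviation around 15), and
the calibration slope of 1.00 says they are neither over- nor under-shrunk.

`fit_baseline("lasso" | "enet" | "ridge" | "alasso", ...)` fits the
comparators, `run_experiment()` / `summarize_experiment()` run replicated
benchmarks, and `run_pipeline()` drives the whole workflow from CSV/TSV
files to a bundle of artifacts (edge list, hub table, coefficient table,
predictions, JSON metadata).

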