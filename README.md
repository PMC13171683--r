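# mlmisim

Monte Carlo simulation study of multiple imputation for two-level
(clustered) data: does imputing with chained random forests or gradient
boosting — adapted to the multilevel structure with cluster-membership
dummy variables — support valid downstream mixed-model inference, and
how does it compare with the standard parametric multilevel approach
(a Bayesian two-level normal model for individual-level variables plus
cluster-level predictive mean matching for cluster-level variables)?

The package is aimed at methodologists and applied researchers in the
social and behavioural sciences who analyze students-in-schools-style
data with linear mixed models and need to choose an imputation
strategy. It provides, as tested building blocks:

* a **generator** for balanced two-level datasets: 12 correlated
  clustered predictors (6 individual-level `X1..X6`, 6 cluster means
  `L1..L6`), per-variable intraclass correlation η² ~ U(0, 0.85), and
  outcomes from a random-intercept or random-slope linear mixed model

  Y_ij = β₀ + Σ β_k X_ijk + Σ β_{6+k} L_ijk + δ₀j (+ δ₁j X_ij1 + δ₂j X_ij2) + ε_ij,

  with β = (0.3, 0.5, 1, 1.5, 0, 0, 0, 0.5, 1, 1.5, 0, 0, 0),
  δ ~ N(0, 1), ε ~ N(0, 10);
* **amputation** mechanisms: cell-wise MCAR, a binned MAR mechanism
  driven by a reference variable (25 equal-width bins, random bin
  weights), and cluster-level MCAR for the `L` variables;
* a **chained-equations engine** (m = 5 imputations) with pluggable
  univariate imputers: `2l_norm` (Kasim–Raudenbush Gibbs sampler with
  heterogeneous within-cluster variances), `2lonly_pmm` (cluster-level
  predictive mean matching, k = 5 donors), `ranger` (300-tree random
  forest, optional PMM), `boost` (gradient boosting), each tree method
  optionally augmented with cluster dummies;
* **analysis & pooling**: REML linear mixed models (lme4), Rubin's
  rules with Barnard–Rubin degrees of freedom;
* a **metrics layer**: type I error / power, bias, SD ratios versus
  complete-data fits, SE calibration, with Monte Carlo standard errors
  (√(p(1−p)/N), SD/√N, SD/√(2N)).

The full factorial design crosses 2 cluster counts (25×40, 50×20;
N = 1,000) × 2 outcome models × 2 mechanisms (MCAR, MAR) × 3 missing
rates (10%, 30%, 50%) = 24 conditions.

## Worked example

```r
library(mlmisim)

cfg <- dgp_config(n_clusters = 25, cluster_size = 40, seed = 42)
d   <- generate_dataset(cfg)
marginal_r2(d)
#> [1] 0.5337947

amp <- ampute_condition(d, mechanism = "MCAR", rate = 0.5, seed = 9)
round(amp$meta$realized[c("X1", "Y", "L1")], 3)
#>    X1     Y    L1
#> 0.469 0.507 0.520

imp <- impute_method(amp, "parametric", m = 5, seed = 3)
pl  <- pool_rubin(fit_imputed(imp, "random_intercept"))
head(pl$pooled[, c("term", "qbar", "se", "p")], 4)
#>          term      qbar        se           p
#> 1 (Intercept) 0.8973768 0.6218534 0.155988202
#> 2          X1 0.8688846 0.2889047 0.020771509
#> 3          X2 1.6038057 0.2982885 0.001014698
#> 4          X3 1.0230325 0.2826342 0.012901004
```

This dataset's realized marginal R² (fixed-effect variance share)
sits a little above the calibrated 0.484 average — it varies across
datasets with the drawn intraclass correlations. After amputing half
the values and imputing with the parametric multilevel method, the
pooled mixed-model fit still detects the nonzero level-1 effects
(X1–X3; true values 0.5, 1, 1.5) while their estimates carry the
extra imputation uncertainty in `se`.

Condition-level comparisons run through `evaluate_condition()`, e.g.

```r
res <- evaluate_condition(25, "random_intercept", "MCAR", 0.5,
                          methods = c("parametric", "ranger"),
                          n_reps = 100, seed = 1)
res$metrics   # rejection rate, bias, sd_ratio, se_calibration + MCSEs
```

The numbered scripts under `analysis/` drive the study: `01` calibrates
the generator's correlation knobs against the target marginal R²
(0.484 / 0.442), `02` verifies nominal type I error on complete data,
`03` runs condition cells (`--cell`, `--reps`, `--methods`), `04`
summarizes a metrics table.

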