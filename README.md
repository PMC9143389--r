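# skinperm

Two-QSAR modelling of skin permeability coefficients in R.

## The problem

The skin permeability coefficient, Kp = J_ss / ΔC_v (steady-state flux
across excised skin divided by the donor concentration difference,
cm/h), is a key quantity in transdermal drug delivery and dermal risk
assessment. QSAR models of log₁₀ Kp from molecular descriptors face a
well-known tension: simple linear models (MLR, PLS) are interpretable
but miss non-linear structure — permeability rises with lipophilicity
(log P) only up to a point and falls again for very lipophilic
permeants, and the sign of the polarity effect depends on whether a
compound is a transporter substrate — while flexible machine-learning
models predict better but explain less.

`skinperm` implements a **two-QSAR scheme** that keeps both: a
predictive **hierarchical support vector regression** (HSVR) — an
ensemble of RBF-kernel SVR members, each trained on its own small
descriptor subset, whose predictions are stacked under a second-level
meta-SVR — alongside an interpretable **PLS regression** on the same
descriptors. The package is aimed at cheminformatics practitioners who
have a descriptor table (CSV) and want the complete modelling and
validation pipeline behind that scheme.

## What the package provides

* **Data model and I/O** — descriptor tables from/to CSV with explicit
  missing-value markers, Kp ↔ log₁₀ Kp transforms, pKa-based ion-class
  assignment (acid / base / neutral / zwitterion relative to pH 7).
* **Preprocessing** — missing-value and invariance filters, Spearman
  rank-correlation collinearity pruning (pairs with ρ² > 0.64 lose the
  member less correlated with the response), and autoscaling
  (centering/scaling by the fitting-set mean and n−1 standard
  deviation), with a JSON-lines provenance log.
* **Partitioning** — PCA chemical-space projection, structural outlier
  designation (N_rot ≥ 8 or N_O ≥ 11, optionally a Mahalanobis rule),
  and a diversity-preserving 4:1 train/test split by greedy
  farthest-point selection, plus Kolmogorov–Smirnov distribution
  reports.
* **Descriptor selection** — a genetic algorithm over descriptor masks
  followed by recursive feature elimination, both scored by
  cross-validated q² of a linear fit (pluggable).
* **HSVR** — `hsvr()` grid-searches ε- or ν-SVR members per subset,
  stacks them under a grid-searched meta-SVR, and returns a classed
  model with `predict`, `print`, `summary`, `residuals`, `plot`
  methods. `assemble_ensemble()` implements the parsimony rule: no
  (m+1)-member combination is ever evaluated before every m-member
  combination has a verdict.
* **PLS** — NIPALS with 10-fold-CV component selection
  (`fit_pls()`), and the published four-descriptor skin-permeability
  equation as a built-in fixture (`published_skin_model()`):

  log Kp = −2.62974 + 1.26972·log P − 0.55661·V_m − 0.554268·⁰χ
  − 0.076344·Jurs_PPSA_1

* **Validation** — the full statistic battery: RMSE, MAE, s, Δ_max,
  r²/q² (both centering conventions), the external qF1², qF2², qF3²,
  the concordance correlation coefficient, through-origin regression
  diagnostics (k, r0², r0′²), the rm² family (both the plain and the
  square-root penalty variants), the combined stringent acceptance
  criteria (`criteria_check()`), 10-fold cross-validation, and
  Y-scrambling (25 repetitions).
* **Synthetic data** — `generate_skin_data()` draws seeded datasets
  with the structure real curated skin-permeation collections show
  (bilinear log P response with a breakpoint at log P = 4, a size
  descriptor pair correlated at r ≈ 0.98, subgroup-signed polarity
  effects, heavy-tailed count descriptors), so the whole pipeline is
  testable without any external download.
* **Workflow** — `run_two_qsar(two_qsar_config(...))` chains all
  stages and writes split CSVs, model JSON, validation reports, and a
  seeded manifest into a run directory.

## Worked example

```r
library(skinperm)

dat   <- generate_skin_data(synthetic_spec(n_compounds = 150, seed = 42))
norm  <- normalize_table(dat$table)
scores   <- pca_project(norm, n_components = 3)
outliers <- flag_outliers(dat$records, dat$table)
keep  <- setdiff(dat$table$compound_ids, outliers)
ki    <- match(keep, dat$table$compound_ids)
split <- diverse_split(scores$scores[ki, ], keep,
                       train_fraction = 0.8, seed = 42)
split
#> Data split: 106 training / 27 test (ratio 3.93:1)

tr <- match(split$train_ids, dat$table$compound_ids)
te <- match(split$test_ids,  dat$table$compound_ids)
x  <- norm$values; y <- dat$records$log_kp

fit <- hsvr(x[tr, ], y[tr],
            subsets = list(c("log_P", "V_m"), c("log_P", "chi0"),
                           c("log_P", "Jurs_PPSA_1")),
            grid = svr_grid(C = 4^(0:4), gamma = 4^(-3:1),
                            epsilon = c(0.05, 0.1)),
            cv_folds = 5, seed = 42)
fit
#> Hierarchical SVR: 3 member(s) + meta-SVR
#>   member 1 {log_P, V_m}: epsilon-SVR (C = 64, gamma = 0.0625, epsilon = 0.1)
#>   member 2 {log_P, chi0}: epsilon-SVR (C = 16, gamma = 0.0625, epsilon = 0.05)
#>   member 3 {log_P, Jurs_PPSA_1}: epsilon-SVR (C = 16, gamma = 0.25, epsilon = 0.1)
#>   meta: epsilon-SVR (C = 64, gamma = 0.0625, epsilon = 0.1)

ps  <- prediction_set(y[te], predict(fit, x[te, ]),
                      train_mean = mean(y[tr]), train_n = length(tr))
rep <- validation_report(ps, set_role = "external",
                         train_ss = sum((y[tr] - mean(y[tr]))^2))
print(rep, digits = 3)
#> Validation report (external set, n = 27)
#>   q2         0.938
#>   qF1^2      0.939
#>   qF2^2      0.938
#>   qF3^2      0.916
#>   CCC        0.964
#>   Delta_max  0.623
#>   MAE        0.232
#>   s          0.282
#>   RMSE       0.288
#>   k          0.911
#>   r0^2       0.929
#>   r0'^2      0.941
#>   rm2        0.930
#>   rm2'       0.935
#>   <rm2>      0.932
#>   delta rm2  0.005
```

The external q² flavours agree and sit near 0.94: the stacked model
generalizes across the hinge in log P that a single linear fit cannot
represent. `criteria_check(train_report, rep)` then evaluates the
combined stringent acceptance rules (all determination coefficients
≥ 0.70, |r² − q²cv| < 0.10, through-origin consistency with
0.85 ≤ k ≤ 1.15, |r0² − r0′²| < 0.30, rm² ≥ 0.65, ⟨rm²⟩ ≥ 0.65 with
Δrm² < 0.20, CCC ≥ 0.85) and reports a per-criterion verdict; on this
fit every applicable criterion is fulfilled.

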