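---
title: "Methods: two-QSAR modelling of skin permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-QSAR modelling of skin permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

The in vitro skin permeability coefficient Kp (cm/h) is the
steady-state flux across excised skin divided by the donor
concentration difference; modelling is done throughout on the signed
log10 scale (`log_kp`), where slow permeants are strongly negative.
The value is stored as printed in curated tables and never negated,
even though the "pKp" naming some sources use would suggest a sign
flip; the package commits to one convention and documents it rather
than guessing intent.

Two models are fitted side by side:

* **HSVR** — an ensemble of RBF-kernel support vector regression
  members, each restricted to a small descriptor subset (a "local"
  view of chemical space), whose predictions form the input of a
  second-level SVR (the meta layer). The stack resolves the tension
  between a broad applicability domain and local accuracy: members
  specialize, the meta layer arbitrates.
* **PLS** — partial least squares regression on the union of the
  members' descriptors, collapsed to signed per-descriptor
  coefficients. PLS tolerates the strong collinearity these
  descriptor sets carry (the two size descriptors V_m and ⁰χ
  correlate near r = 0.98) and stays interpretable where the kernel
  model does not.

The scheme's premise, restated at the level where it is testable on
synthetic data: when the response is bilinear in log P (rising below
a breakpoint, falling above it) with subgroup-dependent polarity
effects, a single global linear fit must underperform the stacked
kernel model on held-out data. The acceptance suite checks exactly
this claim.

## Preprocessing

1. **Missing values** (`drop_missing`): descriptors missing more than
   one value are removed; a single remaining gap is imputed with the
   fitting-set column mean. The imputation rule is the package's own
   choice (the convention in the source literature is unstated); it
   is recorded in the JSON-lines provenance log so no imputation is
   silent.
2. **Invariance** (`drop_invariant`): descriptors with fewer than two
   distinct values or variance ≤ 1e−12 carry no discrimination and
   are dropped.
3. **Collinearity** (`spearman_prune`): squared Spearman rank
   correlation (average ranks for ties) above 0.64 marks a pair as
   redundant — deliberately stricter than the conventional 0.80 cut.
   Pairs are visited in descending pair-r²; the member with the lower
   absolute rank correlation with the response is dropped, ties going
   to the lexicographically later name for determinism. The threshold
   comparison is strictly greater-than: a pair at exactly 0.64
   survives. A `protect` argument exempts descriptors a modeller
   deliberately keeps — the canonical case being near-duplicate size
   descriptors spread across *different* ensemble members, which the
   prune rule would otherwise forbid. The workflow protects exactly
   the descriptors named in explicit member subsets.
4. **Autoscaling** (`normalize_table`): each descriptor is centered
   on its fitting-set mean and scaled by the n−1 standard deviation.
   Test, outlier and external compounds are always transformed with
   the *training* parameters (`apply_normalization`), never
   recomputed, and values outside the training range transform
   without clipping.

**Ion classes.** The four pKa clauses in common use (acid: no pKa
above 7; base: none below 7; zwitterion: strongest acidic pKa above 7
and strongest basic below 7; single-pKa compounds "neutral") overlap
and contradict one another for single-pKa compounds. The package
applies a fixed precedence — zwitterion, then acid, then base, then
neutral — which turns the clauses into a partition: a single acidic
pKa of 4.2 is an acid, an empty list is neutral. This is a
documented operationalization, not an attempt to divine the original
intent.

## Partitioning

Compounds are projected into PC space (`pca_project`, via `prcomp` on
the autoscaled table). Structural outliers are designated by the
reproducible surrogate for visual inspection: N_rot ≥ 8 or N_O ≥ 11,
optionally plus a Mahalanobis distance above the χ²(k) 0.975 quantile
in score space. Outliers are *held out to challenge* the fitted
models, not discarded.

The train/test split (`diverse_split`) targets a 4:1 ratio: the
training size is round-half-away-from-zero of 0.8 × n (91 compounds
give 73/18), and test compounds are chosen by greedy max–min
(farthest-point) selection in PC score space from a seeded random
start, spreading the test set through the occupied chemical space.
The original workflow used a proprietary, undocumented diversity
function; greedy farthest-point is the standard open algorithm with
the same goal. `distribution_report` quantifies the preserved
chemical/biological similarity with two-sample KS statistics and
shared-bin histogram densities.

## Descriptor selection

Two stages, both scored by a pluggable model-quality functional
(default: 5-fold cross-validated q² of an ordinary least-squares
fit):

* `ga_select` — a plain genetic algorithm over binary descriptor
  masks: tournament selection of size 2, uniform crossover, per-bit
  mutation at rate 1/p, one elite per generation (so best fitness is
  non-decreasing), subset sizes kept in range by random repair.
  Population and generation counts (default 30/30) are the package's
  own defaults — the original used a closed-source implementation with
  unpublished settings — and are fully configurable.
* `rfe_select` — recursive feature elimination: every
  leave-one-descriptor-out subset is scored, the descriptor whose
  removal hurts least is purged (exactly one per outer iteration),
  ties broken by dropping the lexicographically later name.

## HSVR fitting

`fit_svr` wraps the libsvm dual solver (ε- and ν-SVR, RBF kernel
exp(−γ‖u−v‖²), inputs used as supplied — autoscale first). The
default lattice for the systematic grid search is C over powers of 4
from 2⁻⁵ to 2¹⁵, γ over powers of 4 from 2⁻¹⁵ to 2³, ε ∈ {0.01, 0.05,
0.1, 0.2} or ν ∈ {0.25, 0.5, 0.75}; the original grid was an
unpublished in-house script, so these bounds follow common libsvm
practice. Ties in the selection score resolve deterministically to
smaller C, then smaller γ, then smaller ε (larger ν) — preferring the
smoother, cheaper model.

**Selection mode.** The original workflow scored grid candidates with
test-set predictions, which leaks held-out information into model
selection. Both modes are provided: `selection = "cv"`
(cross-validated on training rows, the default — honest) and
`selection = "holdout"` (explicit validation set, for comparability).
Neither is asserted to be what the original did, since that is
unstated.

**Parsimony.** `assemble_ensemble` searches member combinations of
size 1, 2, …, `max_members` in order and returns the first
combination that passes the acceptance functional (default: the full
stringent-criteria verdict on training and test predictions of the
stacked model). The evaluation trace is attached to the result — and
to the error condition when nothing passes — so the ordering property
(no size-m+1 evaluation before all size-m verdicts) is checkable, and
is checked in the test suite.

**Numerical notes.** The dual solver's KKT tolerance is the solver
default (1e−3); no randomness enters SVR fitting itself, so seeds
only control fold assignment and permutations. Two degenerate cases
are handled explicitly: a constant (or tube-covered) target yields a
model with zero support vectors, whose regression function is the
constant −rho — predicted as such rather than erroring; and stacking
m identical members reproduces that member only up to the solver's
practical accuracy (~1e−2 on densely clustered meta inputs), not to
machine precision — the test suite asserts the identity at 0.05.

## PLS

`fit_pls` implements single-response NIPALS, fits 1…`max_components`
latent components (default cap min(p, 10)), selects the component
count by 10-fold cross-validated q², and collapses the winner to an
intercept plus per-descriptor coefficients (B = W(PᵀW)⁻¹q). With
k = p components on full-rank data the coefficients coincide with
ordinary least squares, which the tests verify against `lm.fit` and
against an independent PLS implementation.

`published_skin_model()` returns the published four-descriptor
equation (intercept −2.62974; log P +1.26972; V_m −0.55661; ⁰χ
−0.554268; Jurs_PPSA_1 −0.076344) as a fixed model object. Whether
that equation was meant for raw or autoscaled descriptor values is
not stated in its source; the fixture therefore evaluates the printed
affine form on whatever values are supplied, and this ambiguity is
deliberately left visible rather than resolved by guesswork.

## Validation statistics

All statistics operate on a `prediction_set` (observed, predicted,
optional training references). Definitions follow the standard
external-validation literature: residual Δᵢ = yᵢ − ŷᵢ; RMSE with the
n denominator; s as the n−1 standard deviation of residuals (the
source tables never define s; this is the conventional reading);
qF1² centered on the training mean, qF2² on the external mean, qF3²
normalized per-sample with n_EXT and n_TR; CCC as the concordance
ratio penalizing location and scale shifts; k and r0²/r0′² from
through-origin regressions in the Golbraikh–Tropsha formulation
(constrained-fit R² measured about the dependent variable's mean).

Two documented variant switches:

* **r²/q² centering** (`r_squared`): the printed formula in some
  reports centers the denominator on the *predicted* mean; the
  conventional definition centers on the observed mean. Default =
  `observed_mean` (the QSARINS-lineage convention); the as-printed
  variant is selectable.
* **rm² penalty** (`rm2_family`): the as-printed form r²(1 − |r² −
  r0²|) versus the original square-root form r²(1 − √|r² − r0²|).
  Default = `as_printed` for fidelity to the printed equations, the
  sqrt variant selectable. Recomputing the published validation-table
  rm² values from its own r²/r0² columns reproduces them under the
  *sqrt* variant (e.g. 0.58(1 − √0.13) = 0.37), indicating the
  printed equations omitted the radical; the package keeps the
  printed default and exposes both, since only arithmetic on the
  *printed* rm² pairs enters the acceptance checks.

`criteria_check` evaluates the seven combined acceptance rules
(coefficients ≥ 0.70; |r² − q²cv| < 0.10 on training sets;
(r² − r0²)/r² < 0.10 with 0.85 ≤ k ≤ 1.15; |r0² − r0′²| < 0.30;
rm² ≥ 0.65; ⟨rm²⟩ ≥ 0.65 with Δrm² < 0.20; CCC ≥ 0.85), marking a
criterion not-applicable (and excluding it from the overall verdict)
when its statistic is absent — q²cv on external sets, CCC when never
computed. Strict inequalities use a numerical guard: a value whose
distance from the bound is below machine-epsilon scale counts as *at*
the bound and fails, so two-decimal published inputs like
|0.80 − 0.90| sit exactly on the 0.10 bound instead of sneaking under
it in floating point.

Internal validation: `kfold_cv` pools out-of-fold predictions under a
seeded fold assignment and scores them once (not per-fold);
`y_scramble` permutes the response, refits with descriptors
unchanged, and reports the mean training r² over 25 repetitions — a
sound model pairs near-zero scrambled r² with high unscrambled r².

## The synthetic generator

`generate_skin_data` emulates the statistical structure of curated
excised-human-skin permeability collections, not their chemistry:

* log P ~ Uniform(−2, 7) with a continuous hinge response —
  slope +0.5 below the breakpoint at log P = 4, −0.4 above it —
  mirroring the observed rise-then-fall of log Kp with lipophilicity;
* V_m standard normal and ⁰χ constructed to correlate with it at
  r = 0.98 (the near-duplicate size pair);
* Jurs_PPSA_1 standard normal with a ±0.05 coefficient whose sign
  flips between a Bernoulli(0.3) transporter-substrate subgroup and
  its complement;
* a size coefficient of −0.5, additive Gaussian noise with sd 0.3;
* heavy-tailed integer N_rot and N_O counts so a minority of rows
  trips the structural-outlier thresholds.

Effect sizes were chosen once so that a single linear model visibly
underfits while the signal-to-noise ratio stays realistic for log Kp
data (response sd ≈ 1 log unit, noise 0.3); all are configurable, and
none was adjusted after the fact. What the generator does *not*
emulate: real descriptor distributions and their mutual correlations
beyond the stated pairs, chemically valid structures, assay
heterogeneity, or measurement error correlated with chemistry — so
passing tests demonstrate that the machinery recovers the structure
it targets, not that any fitted model transfers to laboratory data.

## Problem sizes and runtime choices

The test and acceptance suites run the synthetic recovery at
n = 300 (240 train / 60 test) over five seeds with a reduced member
lattice (C ∈ 4⁰…4⁴, γ ∈ 4⁻³…4¹, ε ∈ {0.05, 0.1}) and 5-fold
selection CV — sizes at which the full five-seed recovery, including
25 Y-scrambling refits per seed, completes in well under a minute
while leaving the conclusions (test q² ≥ 0.7, gap over the linear fit
≥ 0.05, scrambled r² < 0.15) comfortably clear of their bounds. The
metric battery is verified against independent brute-force summation
on 1000 random 5–20-point prediction sets at tolerance 1e−10.

## Known limitations

* Descriptor *computation* is out of scope: the package ingests
  numeric descriptor tables and does not compute log P, V_m,
  connectivity indices or surface areas from structure.
* The published headline model statistics cannot be reproduced
  without the original 96-compound descriptor values, which are not
  available in text form; acceptance therefore rests on recomputable
  worked values and property-based suites.
* `assemble_ensemble` enumerates combinations exhaustively per size;
  it is intended for candidate pools of the size the parsimony rule
  presumes (a handful), not for large-scale ensemble search.
* The holdout selection mode reproduces a leakage-prone workflow by
  design; its results should not be read as honest generalization
  estimates.
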