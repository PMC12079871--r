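---
title: "Cross-lagged panel network methods in clpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel network methods in clpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpnet)
```

## The model

A cross-lagged panel network (CLPN) describes a two-wave questionnaire panel
as a directed network over its items. For $p$ nodes measured at waves 1 and
2, the edge $i \to j$ is the regression coefficient of node $i$'s wave-1
score predicting node $j$'s wave-2 score, controlling for *all* wave-1 nodes
and for baseline covariates. clpnet estimates it node-wise: one penalized
regression per wave-2 target,

$$\hat\beta^{(j)} = \arg\min_\beta \frac{1}{2n}\big\|y_j - \beta_0 -
X\beta\big\|_2^2 + \lambda_j \sum_k m_k |\beta_k|,$$

where $X$ holds the $p$ wave-1 node scores plus $q$ covariates (standardized
internally to unit variance; coefficients are reported on that scale so that
edge weights are comparable), and $m$ is a 0/1 mask that by default
penalizes covariates like node predictors. The diagonal of the assembled
$p \times p$ matrix holds the autoregressive paths ($i \to i$), the
off-diagonal the cross-lagged edges. Applications of this design
characteristically find autoregressive paths an order of magnitude stronger
than cross-lagged ones, which is why the two families are always summarized
and thresholded separately.

The intended subject matter is symptom-level panels such as generalized
anxiety items (GAD-7) crossed with intolerance-of-uncertainty items
(IUSC-12), but nothing in the machinery is specific to those instruments:
nodes, constructs and response ranges are declared per dataset via
`node_info()`.

## Preprocessing

Item responses are ordinal and typically right-skewed, so before estimation
each node column of both waves is passed through a nonparanormal (Gaussian
copula) transformation: the average-rank empirical CDF $\hat F(x) =
\mathrm{rank}(x)/n$ is Winsorized to $[\delta_n, 1-\delta_n]$ with

$$\delta_n = \frac{1}{4\, n^{1/4} \sqrt{\pi \log n}},$$

mapped through $\Phi^{-1}$, and rescaled to unit sample variance. The
transform is rank-preserving and invariant to positive affine rescaling of
its input; a constant column is mapped to zeros with a warning (every
observation sits at its distribution's median). Descriptive tables
(`descriptive_table()`, with SPSS-convention adjusted skewness and excess
kurtosis and the |skew| > 2 / |kurt| > 7 screening flag) and paired
comparisons are always computed on the *raw* responses; covariates are left
untransformed, since their scaling enters only as regression adjustment.

## Tuning parameters

* **`cv_folds` (default 10).** Folds for selecting $\lambda_j$ by
  cross-validated mean squared prediction error. Fold membership is derived
  from the subject ids and the seed (offset by target index), so estimates
  are reproducible and invariant to row order.
* **`lambda_rule` (default `min_cv_error`).** The minimum-CV rule is the
  convention in CLPN applications; the one-standard-error rule is available
  and yields sparser networks.
* **`lambda_grid_size` (default 100)** over four orders of magnitude down
  from $\lambda_{\max}$, the smallest penalty zeroing every penalized
  coefficient.
* **`threshold_rule` (default `mean_abs_nonzero_crosslagged`).** A
  cross-validated LASSO solution at large $n$ retains many near-zero
  coefficients; the reported network keeps cross-lagged edges with
  $|w| \ge$ the mean absolute nonzero cross-lagged weight. The comparison
  is a weak inequality (an edge exactly at the threshold is retained). The
  signed-mean and fixed-value variants are configurable; with predominantly
  positive edges the variants nearly coincide.
* **`n_boot` (default 5000)** resamples for both bootstrap families, and
  `drop_proportions` (default 5%--75% in steps of 5%) for case dropping.
  The CS criterion is $r \ge 0.7$ in at least 95% of subsamples.
* **`subgroup_cutoff` (default 10)**, applied to the screening construct's
  wave-1 sum on the instrument's *native* scoring: the per-item offset
  between stored and native coding is derived from each node's declared
  range, never hard-coded (a GAD-7 item stored 1--4 contributes
  `stored - 1`).

## Prediction centrality

Published CLPN studies summarize node importance as in-prediction (variance
of a node explained by the other nodes' prior values) and out-prediction
(variance of other nodes' later values explained by the node), each at
cross-lagged scope (excluding only the autoregressive path) and
cross-construct scope (excluding also same-construct paths). The original
literature computes these with path-modeling software without printing
formulas; clpnet re-operationalizes them as differences of $R^2$ between
nested *unpenalized* least-squares refits on the LASSO-selected support,
which is the construction that matches the verbal definitions while being
fully specified:

* baseline $M_0$ = covariates + the target's own wave-1 score (the
  autoregressive term stays in $M_0$ even when the LASSO zeroed it, because
  the definitions require it partialed out, not omitted);
* cross-lagged in-prediction of $j$ = $R^2(M_0 \cup W_j \cup X_j) -
  R^2(M_0)$, with $W_j$/$X_j$ the retained same-/other-construct
  predictors;
* cross-construct in-prediction of $j$ = $R^2(M_0 \cup W_j \cup X_j) -
  R^2(M_0 \cup W_j)$;
* out-prediction of $i$ sums, over targets $j$ whose support retains $i$,
  the drop in $R^2$ when $i$ is removed from the full model (a sum, not a
  mean: hub nodes accumulate influence across targets).

Every index is a nested-model $\Delta R^2$: nonnegative (floating-point
negatives above $-10^{-12}$ are clamped to zero) and bounded by its
wider-scope counterpart. Whether this construction numerically equals the
path-software computation used elsewhere is not established; comparisons
across software should treat the indices as rank information.

## Resampling

`bootstrap_edges()` resamples subjects with replacement and re-runs the
*entire* pipeline (transform, estimation, centrality) per resample;
percentile 95% CIs are reported per edge, and difference tests for edges
and centralities use the percentile CI of the bootstrap difference
distribution (unadjusted for multiplicity). A resample with a constant raw
node column is redrawn and counted. `case_drop_stability()` draws
subsamples without replacement at each drop proportion and correlates
subsample statistics with the full-sample ones; the CS coefficient is
reported as the largest *tested* grid proportion meeting the criterion — no
interpolation, so its resolution is the grid's (finer grids are
configurable). Proportion 0 is prepended with correlation exactly 1 by
construction. All resampling streams derive from one root seed and are
logged.

## The synthetic generator

`synthetic_spec()`/`generate_panel()` emulate the statistical structure the
estimator assumes: wave-1 latents from a two-block Gaussian (correlation
0.4 within construct, 0.2 between), wave-2 latents $= B^\top z_1 +$
independent noise, both waves discretized through per-node thresholds into
the declared Likert ranges. The default geometry mirrors a 19-node
(12 + 7) two-construct panel: autoregressive weights 0.15, cross-lagged
density 0.15 with weights uniform on $[0.1, 0.3]$ — echoing the
characteristic order-of-magnitude contrast between autoregressive and
cross-lagged strength while remaining detectable at desk scale. GA-style
thresholds put ~62% of mass in the lowest of four categories, producing the
right-skewed marginals (sample skewness ≈ 1.3--1.6) typical of anxiety
screeners in nonclinical samples; IU thresholds give mildly skewed
five-category marginals. Default noise SDs solve for unit wave-2 latent
variance, keeping both waves on one scale. Covariates are standard normal
with zero effect by default; a confounded variant adds a shared covariate
effect to both waves to exercise covariate adjustment.

What the generator does **not** emulate: item-level measurement models
(IRT), attrition, floor effects beyond what thresholds induce, covariate
distributions of any real cohort, or time-varying dynamics within the
interval. Passing recovery tests therefore demonstrates correctness of the
estimation machinery under its own assumptions, not robustness to real
questionnaire pathologies.

## Recovery scoring and the power analysis

`recovery_metrics()` scores an estimate against the generating matrix over
the off-diagonal cells: sensitivity (true edges detected), specificity
(absent edges correctly absent), and the Pearson correlation between true
and estimated weights (always on the unthresholded weights).
`power_analysis()` repeats generate-estimate-score over a sample-size grid.

Detection semantics are a genuine design choice. The minimum-CV LASSO keeps
many near-zero coefficients at large $n$; scored on the raw support,
specificity at $n = 7000$ sits near 0.5 even though essentially all of
those false edges are far below any interpretation threshold. The
analysis workflow this package implements never interprets that raw
support: the reported network is the thresholded one. `power_analysis()`
therefore scores detection against the estimate's own thresholded network
by default (`detection = "network_threshold"`), with the raw-support rule
available as `detection = "nonzero"`. Under the default spec at
$n = 7000$ (10 replications), mean sensitivity and specificity are at or
near 1.0 and the mean weight correlation ≈ 0.99, so the minimum of the
three means clears the conventional 0.6 adequacy floor exactly as expected
for a well-powered design.

## Numerical choices

* glmnet rescales `penalty.factor` to sum to the number of predictors; the
  penalty passed down is pre-scaled by `sum(mask)/p` so the objective above
  holds exactly as written. Fixed-penalty solutions are solved to
  `thresh = 1e-12` and match an independent coordinate-descent
  implementation to $10^{-6}$.
* Cross-validation is an explicit fold loop over the glmnet path (fold-wise
  MSE averaged across folds), keeping fold assignment caller-controlled
  and avoiding per-fit object overhead in resampling loops.
* Zero-variance predictors are dropped with a warning and reported with
  coefficient 0; a rank-deficient centrality refit drops collinear columns
  with a warning.
* Cohen's d for paired data is $\bar d / s_d$ with the normal-approximation
  CI $d \pm z_{0.975}\sqrt{1/n + d^2/(2n)}$ — a documented convention of
  this package. Attrition checks use Welch's t.
* Edge lists sort by $|w|$ descending with ties broken by (source, target)
  lexicographic order; integer "percent positive" uses round-half-even.

## Problem sizes used in the test suite

The shipped tests exercise the study-scale claims at sizes chosen to keep a
single-CPU run practical while leaving the conclusions unchanged: the
power claim at $n = 7000$ with 10 replications and the default
configuration; support/sign recovery at $n = 5000$ over 5 seeds; edge
stability at $n = 5000$ with 50 subsamples per drop proportion on the grid
{0.1, 0.3, 0.5, 0.7} with 5-fold CV and a 40-point grid; bootstrap CI
coverage with 100 repetitions of 200 resamples at $n = 1000$ on a two-node
latent-scale panel (coverage is a property of the resampling machinery and
is assessed where the estimator is unbiased; on discretized data the
attenuation of latent coefficients would confound the check). Resampling
unit tests use 10--200 resamples with correspondingly widened tolerances.

## Known limitations

* Two waves, complete cases only: missingness is a hard validation error,
  and longer designs are out of scope.
* The centrality operationalization is this package's own; numerical
  agreement with path-software implementations is unverified.
* CS coefficients are grid-resolved, not interpolated.
* Contemporaneous (within-wave) networks, mixed graphical models for raw
  ordinal data, and elastic-net/adaptive penalties are out of scope.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_subjects = 1000, seed = 42)
panel <- generate_panel(spec)
cfg <- clpn_config(n_boot = 200, seed = 1,
                   drop_proportions = seq(0.1, 0.7, by = 0.2))
report <- run_full_analysis(panel, cfg)
report$result
centrality_report(report$centrality)
export_report(report, "clpn_out")
```
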