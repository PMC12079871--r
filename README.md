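# clpnet

Cross-lagged panel network (CLPN) analysis for two-wave questionnaire
panels, aimed at symptom-network research in psychiatric epidemiology —
e.g. how intolerance-of-uncertainty elements and generalized-anxiety
symptoms predict one another across two measurement waves in adolescent
cohorts.

A CLPN represents items as nodes and estimates, for every wave-2 target
$j$, one penalized regression on all wave-1 nodes and baseline covariates:

$$\hat\beta^{(j)} = \arg\min_\beta \tfrac{1}{2n}\|y_j - \beta_0 - X\beta\|^2
  + \lambda_j \textstyle\sum_k m_k|\beta_k|,$$

with $\lambda_j$ chosen by 10-fold cross-validation. The assembled
$p \times p$ coefficient matrix has autoregressive paths on the diagonal
and directed cross-lagged edges off it. Around that core the package
provides:

* validated two-wave panel ingestion (CSV) with dataset-declared node
  ranges and construct membership (`load_panel()`, `node_info()`);
* descriptive/paired-comparison tables and the nonparanormal (Gaussian
  copula) transformation applied before estimation
  (`descriptive_table()`, `transform_panel()`);
* network estimation, mean-weight edge thresholding, and edge summaries
  (`estimate_clpn()`, `threshold_edges()`, `summarize_edges()`);
* in-/out-prediction centrality at cross-lagged and cross-construct scope
  via nested least-squares variance decompositions
  (`compute_centrality()`);
* nonparametric bootstrap CIs with edge/centrality difference tests, and
  case-dropping stability with CS coefficients (`bootstrap_edges()`,
  `case_drop_stability()`);
* a GAD-7-cutoff subgroup sensitivity analysis (`subgroup_analysis()`),
  one-call orchestration (`run_full_analysis()`), and CSV/GraphML/JSON
  export (`export_report()`);
* a latent-Gaussian synthetic panel generator with known cross-lagged
  structure, plus recovery and power analysis (`synthetic_spec()`,
  `generate_panel()`, `power_analysis()`).

See `vignettes/clpn-methods.Rmd` for the model, its assumptions, and every
numerical convention.

## Worked example

```r
library(clpnet)

spec  <- synthetic_spec(n_subjects = 1000, seed = 42)  # 19 nodes: 7 GA + 12 IU
panel <- generate_panel(spec)
panel
#> Two-wave panel: 1000 subjects, 19 nodes (7 GA + 12 IU), 3 covariate(s)

cfg <- clpn_config(n_boot = 0, seed = 1)   # skip bootstraps for a quick look
net <- estimate_clpn(transform_panel(panel), cfg)
net
#> CLPN: 19 nodes, 161 nonzero cross-lagged edges
#>   mean |autoregressive| = 0.121, mean |cross-lagged, nonzero| = 0.070
#>   threshold (mean_abs_nonzero_crosslagged) = 0.0699

summarize_edges(threshold_edges(net))
#> 53 cross-lagged edges: 53 positive (100%), 0 negative
#> ...

recovery_metrics(spec$true_b, net, threshold = net$threshold)[1:3]
#> $sensitivity
#> [1] 0.9464286
#> $specificity
#> [1] 1
#> $weight_correlation
#> [1] 0.9449518
```

The printed summary shows the characteristic CLPN pattern: autoregressive
paths (the diagonal) are clearly stronger on average than cross-lagged
edges, and thresholding at the mean absolute nonzero cross-lagged weight
reduces the dense LASSO solution (161 nonzero coefficients) to the 53-edge
interpretable network. Because the panel is synthetic, the estimate can be
scored against the generating matrix: at n = 1000 the thresholded network
already recovers 53 of the 56 true cross-lagged edges (weights drawn from
[0.1, 0.3]) with no false edges above threshold, and the true-vs-estimated
weight correlation is 0.94.

## Command line

A thin CLI over the same functions lives at `inst/cli/clpn.R`:

```sh
Rscript inst/cli/clpn.R run      --data panel.csv --config cfg.yaml --out results/
Rscript inst/cli/clpn.R simulate --out data.csv --n 2000 --seed 7
Rscript inst/cli/clpn.R power    --n-grid 250,1000,2500 --reps 10 --out curve.csv
```
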