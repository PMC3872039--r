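# lagnet

Does temporal information help when inferring gene regulatory networks from
expression time series? `lagnet` is an R package plus analysis workflow for
answering that question quantitatively. It implements three families of
causal network-inference methods behind one interface and the full
benchmarking protocol to compare them:

* **static** — shrinkage graphical Gaussian model with partial-variance
  edge direction (`ggm_direct_scores`), PC-style significance sweep
  (`pc_sweep_scores`);
* **fixed lag** — L1-path VAR(1) scoring (`lasso_path_var1_scores`),
  hub/leaf-weighted lasso VAR(1) (`weighted_lasso_var1_scores`), two-step
  first-order conditional-dependence scoring (`g1dbn_scores`);
* **adaptive lag** — per-pair lag estimation
  `lag_XY = argmax_l S(X^{t-l}, Y^t)`, `l ∈ {-l_max, …, l_max}`, driving
  time-lagged MRNET (`tl_mrnet_scores`), time-lagged CLR
  (`tl_clr_scores`), and a three-step differential-expression / DPI
  procedure (`td_aracne_scores`).

Mutual information is estimated either under a Gaussian assumption,
`I = -½ log(1 - r²)`, or by a rank-based copula transform with a bivariate
kernel density (`copula_kde_mi`). Every method returns a `p × p`
`score_matrix` (entry *(i, j)* = evidence for *i → j*).

The assessment protocol (`run_benchmark`) samples 5-node subnetworks from a
gold standard, keeps the strongest direction per gene pair, and scores each
ranking by the area under the precision–recall curve: each recall level
`i/P` receives the maximum precision achieving it, and the AUPRC is the
mean over levels. The reported random baseline accounts for the collapse (a
direction-blind method keeps each gold edge with probability ½). Paired
t-tests compare methods per subnetwork; a time-shuffle control verifies that
dynamic methods lose their advantage when time order is destroyed; lag
histograms summarize the estimated lags over true edges.

A seeded generator (`simulate_dataset`) produces lagged linear expression
dynamics `x_i(t) = Σ β_ji x_j(t - l_ji) + ε` on grids shaped like three
classic microarray series — `fly` (45 points × 30 min), `ecoli`
(32 × 10 min), `yeast` (25 × 5 min) — with hubs, non-uniform sampling and
hidden co-regulation confounders as options.

## Worked example

```r
library(lagnet)

d  <- simulate_dataset(dataset_preset("fly", seed = 20260923))
bm <- run_benchmark(d$series, d$gold,
                    build_methods(default_method_set(l_max = 6)),
                    size = 5, count = 100, seed = 20260923)
print(bm)
```

```
benchmark_result: 100 subnetworks, 8 methods
random baseline (expected AUPRC): 0.1781
     tl_mrnet        tl_clr         g1dbn    var1_lasso var1_weighted
       0.8050        0.7964        0.7688        0.7552        0.7458
    td_aracne           ggm            pc
       0.3773        0.2564        0.2099
```

Every dynamic method outranks both static baselines: with white-noise
sources, lagged effects leave almost no contemporaneous correlation for a
static method to use. On any single dataset the static means fluctuate
around the random baseline (0.18; here the GGM drew a favourable network);
averaged over replicate datasets they settle onto it, which is what
`scripts/acceptance.R` measures. The
analysis scripts under `analysis/` run the full study:

* `01_simulate.R` — writes the three preset datasets (plus an
  irregular-grid series and its 30-min resampling) under `results/data/`;
* `02_benchmark.R` — the same benchmark recomputed from the on-disk TSVs,
  with the paired-t significance map;
* `03_shuffle_control.R` — dynamic methods rerun after time-order
  randomization (max deviation from the random baseline: 0.026);
* `04_lag_analysis.R` — lag recovery (planted 2-step lags recovered within
  ±1 step in 99.5% of 200 replicates), the estimated-lag histogram (mode
  exactly at a planted 4-step lag), and the lag-0 pile-up produced by
  hidden co-regulation;
* `05_lmax_tradeoff.R` — on 25-point series, TL-CLR falls from 0.65 mean
  AUPRC at `l_max = 6` to 0.33 at `l_max = 18`, where only
  `n − l_max = 7` samples support each estimate.

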