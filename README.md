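# ziparnet

Microbial interaction networks and community stability from longitudinal
absolute-abundance data.

## What it does

Longitudinal microbiome studies that pair 16S profiling with qPCR total
load yield *absolute* abundances — counts per unit of sample — for dozens
of taxa over a handful of time points in many subjects. `ziparnet` fits a
zero-inflated Poisson autoregressive mixed-effects model to such panels:

- a logistic component models **structural zeros** (taxa truly absent
  from a subject), `logit(p_im) = A_m W_i`;
- a log-linear AR(1) component models the counts of present taxa,

  ```
  log E(Y_imt) = B_m' log(Y_i(t-1) + 1) + C_m' Z_i + pi_m log(Y_im0 + 1) + b_im
  ```

  with a subject random intercept `b_im ~ N(0, sigma_bm^2)` integrated
  out by Laplace approximation, a Chamberlain-type baseline projection
  `pi_m` decoupling the random effect from the lagged design, lasso
  selection of the sparse interaction matrix `B` tuned per taxon by BIC,
  and quasi-Poisson dispersion.

From the estimate of `B` the package derives community stability — a
strict-sense stationary distribution exists when the spectral radius of
`B` is below 1, and smaller radius means a more stable community — and
performs bootstrap network inference: an interaction is *informative*
when its 95% subject-bootstrap confidence interval excludes zero. Two
comparison estimators (penalized Poisson autoregression and penalized
log-normal MAR), a four-scenario synthetic-panel generator, and the
evaluation metrics (MNSES calibration score, TPR/FPR/MCC/F-score over
all candidate edges, zero-proportion CV diagnostic) round out the
toolkit.

## Worked example

```r
library(ziparnet)

# simulate a zero-inflated heterogeneous community (scenario 4):
# 30 subjects, times 0..10, 20 taxa, strong interactions
sim <- simulate_panel(sim_config(scenario = 4, n_subjects = 30,
                                 n_times = 10, seed = 21))
fit <- fit_zipar(sim$panel)
fit
#> Zero-inflated Poisson AR mixed-effects fit
#>   taxa: 20 (6 all-zero)   subjects: 30   transitions: 300
#>   nonzero interactions: 32 of 400
#>   converged: 14/20 taxa   total BIC: 14656.1
#>   spectral radius of B: 0.371

mnses(fit)          # ~1: the fitted mixture moments match the data
#> [1] 1.000933

stability_report(fit$B, label = "simulated")
#> Community stability report [simulated]
#>   taxa: 20
#>   spectral radius: 0.3713 (squared 0.1378)
#>   stationary: yes   margin to unit circle: 0.6287

# which estimated interactions are real? subject-level bootstrap CIs
edges <- bootstrap_edges(sim$panel, n_boot = 100, seed = 7)
summarize_network(edges)
#> Interaction network summary
#>   taxa: 20   informative interactions: 4 (1.00% of 400)
#>   effect-size bins: |B|<0.1=1  0.1<=|B|<0.25=0  0.25<=|B|<0.5=0  |B|>=0.5=3
#>   positive/negative: 4/0
```

The six all-zero taxa are the structurally absent ones of this draw
(their zero-profile entries are 1 or close to it). The spectral radius
quantifies stability: perturb this community and its abundance
distribution returns toward stationarity at a rate bounded by 0.37 per
time step. `compare_stability()` ranks several communities
(e.g. treatment groups fit separately); `export_graph()` writes the
informative-edge network as TSV or GraphML for a viewer.

The same machinery drives the simulation study:

```r
study <- run_simulation_study(scenarios = c(1, 4), n_subjects = 20,
                              n_times = 10, methods = c("zipar", "poisson"),
                              n_reps = 100, seed = 1)
summarize_study(study)
```

Under the benchmark scenario 1 both the mixture model and the Poisson
baseline are calibrated (median MNSES near 1); under zero inflation and
heterogeneity (scenario 4) the baseline's score explodes by an order of
magnitude while the mixture model stays near 1.

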