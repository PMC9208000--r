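# dynetmm — two-part mixed-effects models for dynamic brain networks

`dynetmm` is an R package for model-based analysis of **dynamic functional
brain networks**: time-ordered sequences of weighted connectivity matrices
obtained by sliding-window correlation of regional fMRI time series. It is
aimed at neuroimaging statisticians who want to test hypotheses about how a
phenotype relates to time-varying, whole-brain connectivity and topology —
rather than cluster connectivity states — and to simulate realistic dynamic
networks from a fitted model.

## The model

Edge weights in thresholded correlation networks are semicontinuous: zero
with positive probability, continuous on (0, 1) otherwise. For participant
*i*, dyad (*j*, *k*) and window *t*, with presence indicator R and strength
S, `dynetmm` fits a two-part (hurdle) mixed model:

**Part I (presence)** — logistic mixed model

    logit P(R_ijkt = 1) = X'_ijkt β_r + Σ_o γ_ro s_(o)(t) + Z'_ijkt b_ri + Σ_o d_rio s_(o)(t)

**Part II (strength, given presence)** — Gaussian mixed model on the
Fisher-Z scale

    atanh(S_ijkt) = X'_ijkt β_s + Σ_o γ_so s_(o)(t) + Z'_ijkt b_si + Σ_o d_sio s_(o)(t) + e_ijkt

The fixed design X contains endogenous network covariates computed from the
networks themselves (dyad means of clustering coefficient, nodal efficiency
and leverage centrality, absolute degree difference, window modularity), a
covariate of interest (COI) with COI × network interactions, declared
confounders, and inter-node distance with its square. `s_(o)` is an
orthonormal polynomial basis over window indices capturing the population
temporal trend (γ) and participant-level deviations from it (d). Random
effects use a diagonal variance-components structure — one variance per
family (intercept, network slopes, distance slopes, optional per-node
propensities, polynomial deviations).

Estimation: REML for the strength part (Fisher scoring on the profiled
restricted likelihood, with `lme4` as fallback initializer) and restricted
pseudo-likelihood (iterative linearization around the logit link) for the
presence part. Inference: Wald F tests with residual denominator degrees of
freedom; multiplicity handled by an adaptive (lowest-slope) false discovery
rate step-up. The temporal polynomial degree is selected over a grid by five
information criteria plus an estimate-stability rule. A generative simulator
draws dynamic networks from fitted or user-specified parameters.

## Worked example

Everything below runs from synthetic fixtures; no imaging data is needed.

```r
library(dynetmm)

make_fixtures("demo", preset = "small", seed = 1)   # 6 participants, 10 nodes
cfg <- pipeline_config(
  timeseries_dir  = "demo/timeseries",
  phenotype_file  = "demo/phenotypes.csv",
  coordinate_file = "demo/coordinates.csv",
  out_dir = "demo/results",
  window_length = 30, ar_order = 1,
  coi = "coi", confounders = list(sex = "binary", age = "continuous"),
  poly_degree = 2, simulate_realizations = 5, seed = 42)
res <- run_pipeline(cfg)
res$fits$strength
#> <twopart_fit> strength part: 486 obs, 18 fixed effects, 4 variance parameters
#>   converged: TRUE; restricted log-likelihood 17.76
#>     parameter    estimate          se        p_raw        p_adj
#>   (Intercept) -0.26069613 0.147220873 7.724776e-02 7.724776e-02
#>         C_avg  0.49383275 0.233930666 3.530016e-02 6.098755e-02
#>         E_avg  1.70723601 0.382216932 9.971992e-06 8.974793e-05
#>         l_avg -0.38430869 0.167086441 2.188402e-02 4.923904e-02
#>        k_diff -0.02440592 0.009951142 1.454781e-02 4.923904e-02
#>             Q  0.35139646 0.178218470 4.923039e-02 6.098755e-02
#>           coi -0.42790592 0.181733618 1.895594e-02 4.923904e-02
#>   ...
```

The pipeline wrote a long edge list of the thresholded dynamic networks
(`networks.csv`), the estimate table above for both model parts
(`estimates.csv`, with raw and adaptive-FDR-adjusted p values), the
information-criterion table (`gof.csv`), a run manifest, and — because
`simulate_realizations = 5` — an observed-vs-simulated summary of weighted
network measures:

```r
read.csv("demo/results/simulated_summary.csv")
#>   metric  mean     sd       set
#> 1      C 0.260 0.0768  observed
#> 2  Eglob 0.222 0.0411  observed
#> 3      K 5.400 0.8650  observed
#> 4      C 0.247 0.1041 simulated
#> 5  Eglob 0.264 0.0858 simulated
#> 6      K 4.689 1.1472 simulated
```

Reading: in this toy fit, strength rises steeply with dyad efficiency
(`E_avg`, adjusted p ≈ 9e-5), and the simulator reproduces the observed
networks' mean clustering (C), global efficiency (Eglob) and degree (K)
within their Monte-Carlo spread. On real studies the interesting rows are
usually the COI × network interactions — e.g. a positive `coi_x_Q` would say
the phenotype weakens the (typically negative) coupling between whole-brain
modularity and connection strength.

Lower-level entry points (`build_dynamic_networks()`,
`node_metric_table()`, `dyad_covariates()`, `assemble_design()`,
`fit_twopart()`, `degree_selection()`, `simulate_dynamic_networks()`) expose
each stage separately; `inst/exec/dynetmm` wraps the pipeline for shell use
(`dynetmm make-fixtures`, `dynetmm build-networks`, `dynetmm run --config
config.yaml`).

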