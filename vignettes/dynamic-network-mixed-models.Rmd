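---
title: "Modeling dynamic brain networks with two-part mixed effects"
author: "dynetmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dynamic brain networks with two-part mixed effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynetmm)
```

## The problem

Resting-state functional connectivity is not stationary: correlations between
regional BOLD signals fluctuate on the order of tens of seconds. A *dynamic*
functional network is a time-ordered sequence of connectivity matrices, one
per sliding window over the scan. Most analytic tools for such data are
data-driven (clustering of connectivity states, hidden Markov models).
`dynetmm` instead provides a *model-based*, multivariate framework: it relates
the presence and strength of every connection, in every window, to

- **endogenous** covariates — graph-topology measures computed from the
  networks themselves (clustering coefficient, efficiency, degree difference,
  leverage centrality, modularity), and
- **exogenous** covariates — phenotypes of interest (e.g. a cognitive score)
  and confounders (sex, age, spatial distance between regions, ...),

so that a neuroscientific hypothesis ("does phenotype X modulate the coupling
between whole-brain modularity and connection strength?") maps onto a
specific regression coefficient with a standard error and a p value. The same
fitted model doubles as a generative simulator of dynamic weighted networks.

## From time series to networks

Per participant, the pipeline takes a T × P matrix of region-averaged BOLD
series and

1. **prewhitens** each regional series (AR(p) residualization, default
   p = 1, least squares), because sliding-window correlations of
   autocorrelated series are themselves strongly autocorrelated and would
   distort the regression downstream;
2. computes **sliding-window Pearson correlations** for all region pairs.
   The default window is rectangular (uniform weights) with
   `shift = length`, i.e. non-overlapping windows, which further suppresses
   temporal autocorrelation between successive networks. A per-volume weight
   vector can be supplied for tapered/modulated windows; uniform weights
   reduce exactly to the ordinary Pearson correlation. Window count follows
   `W = floor((T − L)/shift) + 1`; windows never extend past T.
3. **thresholds negative correlations to zero.** Graph measures — clustering
   in particular — are poorly understood on signed graphs, and positive and
   negative edges carry different neurobiological meaning. All downstream
   weights live in `[0, 1)`; exact correlations of 1 (duplicated series) are
   clipped to `1 − 1e−12` so the Fisher Z-transform stays finite.

## Endogenous covariates

Per window, five measures summarize topology. Degree `k_i` is the count of
nonzero edges (a count, not a strength sum, which is what makes the degree
*difference* of a dyad a resilience/assortativity covariate). Weighted
clustering uses the geometric-mean (Onnela) form with weights rescaled by the
network maximum. Nodal efficiency maps each edge to a length `1/w` and
averages inverse shortest-path distances (`1/∞ = 0`); global efficiency is
its node mean. Leverage centrality is the mean normalized degree contrast
with neighbors, `mean((k_i − k_j)/(k_i + k_j))`, set to 0 for isolated
nodes where the formula is undefined. Modularity `Q = Σ_c (e_cc − a_c²)` is
evaluated at a partition found by seeded Louvain maximization; the package
also recomputes Q from scratch for any partition, which the test suite uses
as an independent check.

Dyad-level covariates are the within-pair means of clustering, efficiency and
leverage, the absolute degree difference, the window's modularity, and the
Euclidean distance between node centroids (mm) plus its square — distance
being a standard geometric confounder of connectivity. Whether the source
networks should be weighted or binarized, and whether degree difference
should be signed, are not settled questions; the package computes weighted
metrics and absolute differences, and both choices are isolated in
`node_metric_table()` / `dyad_covariates()` should a user want variants.

## The two-part model

Edge weights are semicontinuous: exactly zero with positive probability
(absent) and continuous on `(0, 1)` otherwise. A hurdle decomposition models
each component on its natural scale. Writing `R_ijkt` for presence and
`S_ijkt` for strength of the dyad (j, k) of participant i in window t:

**Part I (presence).** A logistic mixed model
`logit P(R_ijkt = 1) = X'_ijkt β_r + Σ_o γ_ro s_(o)(t) + Z'_ijkt b_ri + Σ_o d_rio s_(o)(t)`.

**Part II (strength).** On the rows with `R = 1`, a Gaussian mixed model for
the Fisher-Z transformed weight
`atanh(S_ijkt) = X'_ijkt β_s + Σ_o γ_so s_(o)(t) + Z'_ijkt b_si + Σ_o d_sio s_(o)(t) + e_ijkt`.

The fixed design `X` holds the intercept, the five endogenous terms, the
covariate of interest (COI), COI × network interactions, confounders
(reference-cell dummies for categoricals, first declared level as
reference), and distance plus squared distance. `s_(1..n)` is an
**orthonormal polynomial basis** over the window indices 1..T: QR
orthonormalization of the centered monomials, unit Euclidean norm, each
column orthogonal to the constant vector (the model intercept plays the
degree-0 role) and signed so the leading coefficient is positive.
Orthonormal rather than natural polynomials keep the columns
well-conditioned at degrees in the teens. The population-level γ terms carry
the shared temporal trend; participant-level `d_io` deviations (one
independent variance per degree) let individual trends wander around it.

Random effects use a **variance-components structure**: every family —
participant intercept, each network slope, the distance slopes, each
per-node connection propensity, each polynomial deviation — has one
independent variance shared across participants. Nodal propensities are
implemented but off by default: with hundreds of nodes they are the classic
source of non-convergence. Under the full specification with P = 268 nodes
that structure has 276 non-polynomial variance parameters per part
(1 + 5 + 2 + 268), which `count_variance_parameters()` reproduces.

## Estimation

The strength part is a weighted linear mixed model fit by REML. Because all
random terms are scalar-per-participant, each participant's covariance block
is `W_i^{-1} + U_i diag(λ) U_i'` with `λ = τ/σ²`, and every trace in the
restricted-likelihood gradient and expected information reduces to scalar
products via the Woodbury identity and the rank-1-per-block structure of
`Z_k Z_k'`. `fit_weighted_lmm()` exploits this: it runs Fisher scoring on the
profiled REML surface (σ² profiled out, λ ≥ 0 by projection, step-halving on
the restricted likelihood) from a warm start, falling back to `lme4::lmer()`
for a robust starting point when scoring stalls. Scoring with analytic
gradients localizes variance components to ~1e−11 — derivative-free
optimizers stall near 1e−7 because the profiled deviance is flat below
double-precision noise there — and is an order of magnitude faster at the
problem sizes the recovery suite uses.

The presence part is estimated by **restricted pseudo-likelihood**: starting
from a fixed-effects-only logistic fit, form the working response
`ν = η + (R − μ)/(μ(1 − μ))` and weights `μ(1 − μ)`, fit the weighted REML
model above, update `η` including the predicted (BLUP) random effects, and
iterate until the joint relative change in fixed effects and variance
components drops below 1e−6 (at most 100 outer iterations; hitting the cap
flags the fit rather than failing silently). With all variance components
pinned at zero the loop is exactly iteratively-reweighted least squares and
reproduces the ordinary logistic MLE, an equivalence the tests assert at
1e−6. A linear predictor exceeding ±30 on the logit scale aborts with a
complete-separation diagnosis.

**Inference** uses the Wald F statistic
`F = (Lβ̂)'(L V̂ L')^{-1}(Lβ̂)/rank(L)` with the residual
degrees-of-freedom approximation `df_den = N − rank(X)` (no
Kenward–Roger/Satterthwaite adjustment — at the row counts involved the
residual approximation is standard and cheap). Table-wide p values are
adjusted by an **adaptive FDR** procedure: the number of true nulls `m0` is
estimated by the lowest-slope method on the ordered p values and substituted
for `m` in the Benjamini–Hochberg step-up; with `m0 = m` the adjustment is
plain BH exactly.

**Goodness of fit and degree selection.** AIC, BIC, AICc, HQIC and CAIC are
computed from the restricted (strength) or final working-model
(presence — a pseudo-likelihood, so cross-family comparisons carry the usual
caveat) log likelihood with `K` = fixed effects + covariance parameters.
`degree_selection()` fits both parts at every degree of a grid (the
classical whole-brain analysis uses 3–18, sixteen fits), tabulates the five
criteria and the COI-related estimates, and formalizes "consistency of
estimates" as: the longest contiguous run of degrees in which every
consecutive pair of key-estimate vectors changes by less than 10% relative
(denominator floored at 0.01 so near-zero estimates do not dominate); the
chosen degree is the floor-midpoint of that run, ties to the earlier run.
Degrees that fail to fit are recorded and skipped, not fatal.

## Simulation

`compute_moments()` evaluates, per design row, the population presence
probability `p = logistic(X'β̂_r + Σ γ̂_ro s_(o))`, the strength mean
`μ_sim = X'β̂_s + Σ γ̂_so s_(o)` and the marginal strength variance
`σ²_sim = Σ_k τ̂_bs,k z_k² + Σ_o τ̂_ds,o s_(o)² + σ̂²` on the Fisher-Z
scale. `simulate_dynamic_networks()` draws, per participant and realization,
one random-effect vector per part from `N(0, diag(τ̂))` — the two parts are
estimated independently, so their draws are independent; realizations within
a participant redraw the effects, each being an independent network sample —
then presence from Bernoulli(p) and strength from the conditional normal,
back-transformed by `tanh` and masked by presence. Negative back-transformed
strengths on present edges (the observed networks are nonnegative by
construction, so the model is silent about them) are truncated to zero by
default with the truncation rate logged (typically 1–2% under the default
ground truth); a diagnostic mode retains them. A master seed spawns one
substream per (participant, replicate), so any subset of the output is
reproducible in isolation, and repeated runs are bit-identical.

## The synthetic-study generator

Tests and recovery experiments need data whose generating parameters are
known. `make_ground_truth()` fixes a full parameter set; its defaults are
deliberate choices, not tuning knobs:

- study dimensions default to N = 40 participants, P = 20 nodes, W = 6
  windows, polynomial degree 2 — large enough for mixed-model asymptotics to
  be meaningful, small enough for a 50-replicate recovery study to run in a
  few minutes on one CPU;
- the residual SD of Fisher-Z strengths is 0.1, about the sampling noise of
  a 120-volume window correlation (`1/sqrt(L − 3) ≈ 0.09`);
- the planted effects include a presence-model COI coefficient of 0.3 and a
  strength-model COI × modularity interaction of 0.03 — the headline effect
  structure of a phenotype-modulates-topology analysis — alongside exact
  zeros on the remaining interactions so null calibration is checkable;
- participant random-intercept variances are 0.25 (presence, logit scale)
  and 0.01 (strength, Fisher-Z scale); polynomial-deviation variances 0.04
  and 0.0025; coordinates are uniform in a 100 mm cube so the distance
  confounders are well defined.

`generate_synthetic_study()` first draws auxiliary correlation networks per
(participant, window) — sixty-sample correlation matrices of a latent
three-community factor model whose factor loading varies by window, then
thresholded — so the endogenous covariates (modularity especially) vary
realistically across windows. The design table is assembled through the same
code path as real data, then presence and strength are replaced by draws from
the generating two-part model. Two divergences from real data are deliberate
and documented: the covariates are *regressors* taken from the auxiliary
networks, not recomputed self-consistently from the simulated edges (the
model treats topology as given, and recovery testing does not require
self-consistency); and the rare present edge whose strength draw
back-transforms negative is floored at 1e−6 so the hurdle consistency
`R = 1 ⇔ Y > 0` holds exactly. Consequently passing recovery shows the
estimation machinery is correct *for the model's own data-generating law*;
it does not certify behavior under real-data violations such as
metric-edge feedback, spatial autocorrelation of residuals, or scanner
artifacts.

At those defaults, 50 replicates give nominal-95% Wald coverage between
0.86 and 1.0 across all fixed effects of both parts, aggregate
|bias|/empirical-SE around 0.12–0.13, and the planted interaction is
detected (adaptive-FDR adjusted p < 0.05) in about two thirds of
replicates — all recomputed, not quoted, by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`.

## Numerical and degenerate-input policy

- Constant node series: rejected at prewhitening (the node is named); inside
  a single window, that node's correlations are set to 0 with a warning.
- Weights are clipped to `[0, 1 − 1e−12]`; `fisher_z` rejects |y| ≥ 1.
- Singular fixed designs are rejected naming the collinear columns; an
  all-present or all-absent presence response is a hard error.
- Variance components are constrained nonnegative; boundary estimates
  (exact zeros) are legitimate results, not failures.
- AICc is reported as missing when `N ≤ K + 1`.
- The simulator-calibration check compares generator-route and
  simulator-route network summaries at 30 participants × 4 windows with 10
  realizations; at materially smaller sizes the Monte-Carlo spread of the
  metric means exceeds the agreement band the check asserts.

## Known limitations

- The presence part is a pseudo-likelihood method; its "log likelihood" (and
  hence GOF values) are comparable across degrees within the same data and
  structure, not across datasets, and PQL-type estimators carry a small
  attenuation bias for binary outcomes with small cluster sizes.
- Nodal-propensity random effects are structurally supported but not
  performance-guaranteed at hundreds of nodes.
- The modulated (tapered) window shape is pluggable but no specific taper is
  shipped; the default is rectangular.
- Cross-part correlated random effects are out of scope; the simulator
  treats the parts as independent.
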