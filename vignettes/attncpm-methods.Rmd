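---
title: "Methods: from stop-signal behaviour to connectome prediction and latent change"
author: "attncpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stop-signal behaviour to connectome prediction and latent change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements, the assumptions behind each stage, and the design decisions
taken where the methodology leaves room. The pipeline has six stages:
synthetic data generation, stop-signal behaviour, gPPI connectivity,
connectome-based predictive modelling (CPM), substance-use factor scores,
and a bivariate latent change score (LCS) model.

## The phenotype: intra-individual coefficient of variation

Sustained attention is summarized per subject as the intra-individual
coefficient of variation of go reaction times, `ICV = SD(go RT) / mean(go
RT)`; lower values mean steadier responding. Two decisions were open and are
configurable:

* **Valid go RTs.** A valid RT is a responded go trial with the correct
  side; omissions and choice errors are excluded from the RT pool
  (`includeChoiceErrors = FALSE` by default). The published exclusion rules
  operate on subjects, not trials, so the trial-level rule is ours.
* **Denominator.** The sample SD (n − 1) is used, the convention for
  per-subject variability estimates.

Subject-level quality control excludes subjects with more than 20% go
errors or mean framewise displacement above 0.5 mm; both are strict
inequalities, so a subject sitting exactly on a threshold is retained.

## Stop-signal simulation

The generator implements the standard horse race: go RTs and stop-signal
RTs (SSRT) are lognormal (positive and right-skewed, matching empirical RT
shape), and a stop trial is inhibited iff the go RT draw exceeds SSD +
SSRT draw. The SSD staircase moves +50 ms after a successful stop and
−50 ms after a failed one, clamped to the 250–900 ms grid; the starting
value is not specified by the task description, so the generator defaults
to the on-grid midpoint (550 ms) and records it. Go-trial spacing draws the
number of go trials between successive stops uniformly from {3, …, 7} and
repairs the sequence by unit steps inside that range until the go-trial
budget is met exactly.

The default race parameters (go mean 520 ms, SD 130; SSRT mean 200 ms, SD
50; 2% omissions and choice errors) place the tracking equilibrium — the
SSD at which inhibition succeeds half the time — near 310 ms, comfortably
inside the staircase grid. A static simulee does not slow down
strategically the way real participants do, so the long-run success
proportion settles slightly below one half (about 0.47 over 10,000 stop
trials); post-stop slowing and other sequential effects are deliberately
not modelled.

## gPPI connectivity

For each ordered ROI pair, a GLM regresses the seed BOLD series on the
partner series (physiological term), the HRF-convolved task regressors
(three in the go-trial model: GO, failed stop, successful stop; two in the
successful-stop model, go trials acting as implicit baseline), one
interaction (PPI) term per condition, the 36-column nuisance expansion
(6 motion + 3 tissue channels, their backward-difference derivatives, and
the squares of both), and a 128 s discrete-cosine high-pass basis. The
matrix entry is the PPI coefficient of the condition of interest, and the
directed matrix is symmetrized as `(M + t(M)) / 2` with a zero diagonal.

Numerical and interpretive choices:

* **Canonical HRF.** Double-gamma (peak ≈ 5 s, undershoot ≈ 15 s, 1/6
  amplitude), unit peak. Task regressors are built on a TR/16 microtime
  grid and sampled at volume onsets.
* **PPI term.** The partner series is deconvolved to the neural level by
  ridge-regularized inversion of the HRF convolution operator (penalty per
  series by generalized cross-validation over a log-spaced grid, one SVD
  shared across ROIs), multiplied by the *uncentered* 0/1 condition
  indicator (centering is an option), and re-convolved with the HRF. The
  last ~kernel-length samples of a deconvolved series are causally
  unobservable and are shrunk to zero; the round-trip is exact to <1e-6
  relative error on the identifiable interior.
* **Which coefficient fills the matrix.** The published equations mention
  "one contrast term" without defining it; the package takes the PPI
  coefficient of the condition of interest (GO for the go-trial model, SS
  for the successful-stop model), configurable via `ppiOf`. This is the
  principal interpretive decision of the module.
* **High-pass filtering** is implemented by including the cosine basis as
  regressors, equivalent to filtering within the GLM.
* Conditions without any event (possible in short simulated runs) would
  contribute all-zero regressors; they are dropped from that run's design.

## Connectome-based predictive modelling

Edge selection computes, per upper-triangle edge, the partial Pearson
correlation between edge value and phenotype controlling the covariates
(age, sex, scan site as reference-coded dummies, mean FD): both sides are
residualized on the covariate design and the residual correlation is
tested with `df = n − 2 − k`. Edges with two-sided `p < 0.01` (the
selection threshold; configurable) form the positive and negative networks
by sign. Network strength sums the selected edges once each; the combined
network is positive minus negative strength. Per network, a linear model
`phenotype ~ strength + covariates` is fitted on training subjects and
applied to held-out subjects.

Cross-validation supports 10-fold and 5-fold schemes (random partitions,
optionally site-stratified, 50 repeats by default) and leave-site-out
(folds are scan sites, deterministic). Performance per repeat is the
correlation between concatenated out-of-fold predictions and the observed
phenotype; the headline number is its mean over repeats. Consensus edges
are those selected in *every* fold of a repeat, in at least
`ceiling(0.95 × repeats)` repeats — 48 of 50 at the defaults.

Permutation inference reruns the entire pipeline, selection included, with
the phenotype–connectome correspondence shuffled (covariates stay attached
to the connectomes). The observed statistic and every null rerun use the
same scheme under the same fold partition, drawn once from the seed; this
makes observed and null values exchangeable under the null, which is what
the uniformity of the resulting p-values rests on. One CV split per
permutation is the default (a `nRepeats` flag averages several), and the
add-one estimator `p = (1 + #{null ≥ obs}) / (nPerm + 1)` avoids p = 0.
Because edge residualization never involves the phenotype, all
permutations within a fold share one matrix factorization; the batched
engine is numerically identical to naive reruns.

Model transfer across cohorts applies a source model's edge sets and
linear coefficients to a target cohort (`"coefficients"` mode) or
correlates covariate-residualized strength with the phenotype
(`"residual_correlation"` mode); significance comes from shuffling the
predicted values 1000 times. Transfer models are trained on the full
source sample. Unseen site levels in the target are an error, never
silently zeroed.

## Substance-use factor scores

Adequacy diagnostics are the KMO statistic (overall and per item, with
items below 0.5 flagged for exclusion) and Bartlett's sphericity test
(`χ² = −(n − 1 − (2p + 5)/6) log|R|` on `p(p − 1)/2` df). Extraction is
principal-component: eigendecomposition of the item correlation matrix,
loadings scaled by the square roots of eigenvalues, Kaiser retention
(eigenvalue > 1) by default with a fixed-count override — the published
analysis reports factor counts but not its retention rule. Varimax
rotation with Kaiser normalization is delegated to `stats::varimax`
(tolerance 1e−8); rotation is orthogonal and leaves communalities and the
reproduced correlation matrix unchanged. Factor scores use the regression
method, `Z R⁻¹ Λ`, on items standardized with the training moments;
complete-case analysis throughout (the published workflow excluded items
rather than imputing).

## Bivariate latent change score model

Two constructs observed at three waves, single indicators with measurement
error fixed at zero (standard for observed-variable LCS). The latent
change over each interval is regressed on the previous-wave level of the
same construct (self-feedback β) and the other construct (coupling γ);
with the default equality constraints across the two intervals the model
has 14 free parameters against 27 sample moments (13 df). The
model-implied mean and covariance of the six observables follow in closed
form from the state recursion `s_{t+1} = a + A s_t + z_t`.

Estimation minimizes the multivariate-normal discrepancy
`F = log|Σ| + tr(SΣ⁻¹) + (m̄ − μ)′Σ⁻¹(m̄ − μ) − log|S| − 6`
by BFGS from a moment-based start (initial moments from the data, dynamics
from pooled OLS of observed changes on previous-wave scores) plus
seed-controlled jittered restarts; inadmissible parameter sets
(non-positive-definite blocks) are rejected inside the objective.
`χ² = (n − 1) F` at the optimum; standard errors come from the inverse
observed information `((n − 1)/2 × Hessian of F)`; standardized
coefficients rescale by the implied SDs of the predictor and of the latent
change. Fit indices: CFI against the independence baseline
(`χ²_b = −(n − 1) log|R|`, 15 df), `RMSEA = sqrt(max(χ² − df, 0)/(df (n −
1)))`, and SRMR as the RMS standardized covariance residual over the 21
unique elements.

Covariates (age, sex, site) are residualized out of all six observed
columns *before* fitting rather than entered as exogenous predictors; this
mirrors the residualization practice used for the correlation analyses,
keeps the model identified with six observables, and is the module's
principal deviation risk — both routes are defensible, and the
residualization route was chosen for parsimony. Change-residual
covariances are freely estimated within wave. Listwise deletion handles
missing waves.

An independently written scipy implementation of the same model (its own
moment propagation and optimizer) agrees with the package on a fixed
synthetic dataset to ~1e-5 in estimates and to 1e-6 in the fit indices;
those values are frozen in the test suite.

## What the generators emulate — and what they do not

Every generator is a pure function of parameters and seed, emits its
ground truth alongside the data, and no test reads truth through the
analysis path.

* **Connectome cohorts.** Null edges are independent standard normal;
  planted edges share a latent network factor on which the phenotype also
  loads, calibrated so each planted edge has population partial
  correlation ≈ 0.3 with the phenotype. A phenotype built as a plain sum
  of 40 *independent* edges cannot reach per-edge correlations of 0.3 (the
  squared correlations would sum past one), so shared edge variance is the
  realistic structure — edges of one functional network co-vary. Site and
  covariate shifts can be added to edges and phenotype; they carry no
  information about the factor, so residualization removes them.
* **ROI time series.** Condition activations through the canonical HRF,
  AR(1) background neural fluctuations (coefficient 0.3 by default,
  configurable), planted interaction effects at the neural level, AR(1)
  measurement noise, and matched motion/tissue nuisance channels. No
  volumetric images, physiological noise, or scanner artefacts are
  simulated.
* **Latent change cohorts** are simulated directly from the LCS structural
  equations; **substance items** from a linear factor model with optional
  flooring at zero to mimic consumption counts.

Passing tests therefore demonstrate correctness of the estimators under
the generators' assumptions (linearity, Gaussian noise, correctly
specified dynamics), not robustness to the messier features of real
neuroimaging cohorts (scanner drift, distribution shift between sites,
skewed consumption counts, missingness).

## Problem sizes and calibration conditions used by the test suite

The suite exercises the statistical claims at sizes chosen to keep the
full run in minutes while leaving Monte-Carlo error well inside the
asserted tolerances: staircase calibration over 10,000 stop trials;
selection and permutation calibration over 200 replicate null cohorts
(n = 300 subjects, 60 nodes) with 200 permutations of a 5-fold split each;
planted-signal recovery on cohorts with 40 edges at |r| ≈ 0.3; gPPI sign
recovery over 30 simulated runs; LCS recovery over 100 replicates at
n = 2000 (coupling 0.12) and 100 null replicates at n = 1000. The demo
pipeline runs 100 subjects on a 40-node atlas with reduced repeats and
permutations.

## Known limitations

* The gPPI estimate of a planted interaction is attenuated (shape, not
  scale, is recovered through regularized deconvolution); sign and
  ordering are the reliable quantities.
* The permutation null is conditional on the fold partition; with very
  small cohorts the discreteness of the partition can show.
* The LCS fitter assumes multivariate-normal observables; heavy floors in
  consumption scores should be factor-scored or transformed first.
* Full-information ML for missing waves and oblique rotations are listed
  extensions, not implemented.
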