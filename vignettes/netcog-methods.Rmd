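---
title: "Methods: linking structural brain networks to general cognitive function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking structural brain networks to general cognitive function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`netcog` implements a complete analysis chain relating individual
structural connectomes to a latent factor of general cognitive function
(*g*), as used in large multi-cohort neuroimaging studies:

1. **Reference network**: per-cohort consistency thresholding of
   streamline-count networks to a fixed density, then intersection of the
   cohort masks.
2. **Graph metrics**: weighted mean edge weight, global efficiency, mean
   clustering (global) and local efficiency (nodal) on the masked
   networks.
3. **Latent g**: a one-factor confirmatory factor model of the cognitive
   battery, estimated by full-information maximum likelihood (FIML).
4. **Associations**: MIMIC-style structural regressions of *g* on each
   network metric, adjusted for age, sex and site.
5. **Pooling**: three-way random-effects meta-analysis (REML) with
   Benjamini–Hochberg FDR control per metric family.
6. **Prediction and reporting**: edge-wise composite scores evaluated in
   an untouched hold-out half, cross-cohort agreement, hemispheric
   symmetry, and hemisphere/lobe edge classification.

Because the cohort data such a study uses are access-restricted, the
package ships a synthetic-data generator that reproduces the statistical
structure the analysis assumes; every stage is exercised and tested
end-to-end on generated data.

# Data model

Networks are $85\times85$ symmetric nonnegative matrices over a fixed
atlas (34 left + 34 right Desikan–Killiany cortical regions, $8+8$
subcortical structures, brainstem last). Node order is frozen in the
packaged atlas table and indices are 0-based in all files and APIs. Edge
order is canonical: pairs $(i,j)$, $i<j$, sorted by $i$ then $j$ (3570
pairs). Weightings: SC (streamline count, unitless), FA (fractional
anisotropy, $[0,1]$), MD (mean diffusivity, $10^{-3}\,$mm$^2$/s), and SD
(streamline density — SC divided by the *sum* of the two endpoint region
volumes, a documented convention since only "the corresponding grey
matter regions" is standard language). FA and MD are zero wherever SC is
zero: no streamline means no sampled diffusion value. This coupling is an
assumption — original tractography pipelines do not state it — and is
enforced by the generator and validated on load.

# Reference-network construction

Consistency thresholding ranks all 3570 node pairs by the coefficient of
variation (CV = SD/mean) of the SC weight across participants and keeps
the `K = round(density * 3570)` lowest-CV pairs (ties: higher mean
weight, then lexicographic). At the default density 0.30 this keeps
exactly 1071 pairs. Two choices deserve note:

* **Zeros are included** in the per-edge mean and SD: an absent
  connection is zero streamlines. Excluding zero-weight participants
  would make rare edges look spuriously consistent. The zeros-excluded
  variant is available (`consistency_table(zeros = "exclude")`).
* **CV is computed on SC only** and the resulting mask applied to SC, FA
  and MD alike, following the convention of the consistency-thresholding
  literature.

Cohort masks are intersected to form the reference network; the result
records pairwise overlap counts. Thresholded masks are nested across
densities, and intersection is commutative/associative/idempotent — both
properties are tested.

# Graph metrics

Edge lengths are reciprocal weights, $l_{ij} = 1/w_{ij}$, for **all**
weightings including MD. MD-weighted networks are analysed on their raw
weights with no inversion; their associations with *g* are therefore
expected to be negative, which matches how such studies report MD
metrics. Global efficiency is
$E = \frac{1}{n(n-1)}\sum_{i\ne j} d_{ij}^{-1}$ with $d_{ij}$ the
shortest weighted path length (Dijkstra on the dense matrix, implemented
in C++); unreachable pairs contribute zero. Clustering uses the Onnela
geometric-mean form on weights max-normalised per participant,
$C_i = \sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} / k_i(k_i-1)$,
zero for degree $<2$. Local efficiency for node $i$ restricts shortest
paths to the subgraph induced by $i$'s neighbours and combines
$(\hat w_{ij}\hat w_{ih}/d_{jh}(N_i))^{1/3}$ over ordered neighbour
pairs. Several descendant variants of the weighted local-efficiency
formula exist in the literature; the one implemented here is stated
above, and all three metrics are verified against brute-force
Floyd–Warshall / exhaustive-triple oracles to $10^{-10}$ on random small
graphs.

# The g measurement model

Scores $x_j = \nu_j + \lambda_j g + \varepsilon_j$ with $g\sim N(0,1)$
(latent variance fixed to 1, all loadings free, first loading positive)
and $\Theta$ diagonal apart from user-specified residual covariances —
one pair for a short five-test battery, within-domain blocks for a long
battery, mirroring how real cohort batteries are modelled. The casewise
FIML log-likelihood sums each participant's observed-variable pattern;
rows with no observed tests are dropped and reported. Optimisation is
BFGS on free parameters with log-parameterised residual variances
(relative tolerance $10^{-10}$, maximum 500 iterations); non-positive-
definite proposals are rejected inside the likelihood. The saturated
reference for fit indices is estimated by EM under missingness; the
independence baseline is per-variable Gaussian ML. CFI, TLI and RMSEA
follow the standard likelihood-ratio formulas; SRMR is computed on the
correlation metric from listwise-complete moments, a documented
approximation under missingness. Factor scores use the regression method
per missingness pattern and are standardised.

# Structural regression

The primary estimator is a one-step MIMIC model: the measurement part
above plus $g = \gamma^\top C + \zeta$, where $C$ stacks the standardised
metric, standardised age, sex (0/1), and site dummies (first site
reference; single-level site is dropped). Identification switches to a
marker loading ($\lambda_1 = 1$, latent residual variance free), and the
reported coefficient is fully standardised,
$\beta = \gamma_{\text{metric}} / \mathrm{sd}(g)$ with
$\mathrm{sd}(g) = (\gamma^\top S_C\,\gamma + \psi)^{1/2}$; its standard
error comes from the observed information via the delta method. Age
moderation adds a standardised age $\times$ metric interaction ("per SD
of age"); cohorts whose age SD falls below 3 years are skipped with a
flagged row, since the moderator is essentially constant there.

A two-stage fallback (`estimator = "fs"`) regresses factor scores on the
same covariates with a reliability disattenuation: regression scores
satisfy $\hat g = \rho^2 g + e$ with
$\rho^2 = \lambda_o^\top\Sigma_{oo}^{-1}\lambda_o$ per missingness
pattern, so OLS slopes are divided by the mean $\rho^2$ to target the
same standardised quantity. The two estimators agree within $\pm0.02$ at
$n \ge 2000$ on generated data (tested). The fallback is vectorised
across metric columns via Frisch–Waugh residualisation, and is the
practical choice at the node (85) and edge (~800) scales where thousands
of fits are needed; the pipeline defaults to the one-step SEM for the
three global metrics and the vectorised fallback for node/edge scales.

# Meta-analysis and FDR

Cohort coefficients are pooled under the random-effects model with
$\tau^2$ estimated by REML (via metafor, which is also what applied work
uses), Wald intervals and two-sided normal p-values. With only three
cohorts REML can fail to converge; the DerSimonian–Laird moment
estimator is then used and flagged in the output rather than silently.
An independent grid search of the restricted likelihood verifies the
pooled coefficient to $10^{-6}$ in the tests. FDR families are one per
weighting $\times$ scale (e.g. the 85 SC nodes; the FA edges), a
documented decision since the original analysis does not name its
families; the boundary is configurable.

# Composite prediction

Edges are standardised within the evaluated sample (column z-scores) and
combined as $\sum_k \beta_k z_k$ with meta-analytic weights; a strict
out-of-sample mode standardises with training-sample moments instead
(`standardization = "train"`). The first synthetic cohort is split in
half: associations and meta-analysis see only the first half, the second
is an untouched hold-out. At 8000 participants per half, the
training/hold-out correlation difference is a few hundredths (tested at
$<0.05$), emulating main-versus-hold-out stability.

# The synthetic generator

The generator's defaults define the emulated study conditions:

* three cohorts — large/wide-age/4-site ($n=2000$ default, scaled to 800
  in the default pipeline run), small/wide-age/2-site (500/400), small/
  narrow-age/1-site (400/300) with age ranges 45–83, 26–84, 71–74 years;
* cohort network densities 0.35/0.32/0.30 and weight scales 1.0/0.9/0.8,
  standing in for scanner-related density and weight differences;
* batteries of 10/5/13 tests with loadings spanning 0.28–0.73, 10% MCAR
  missingness, and residual covariances (one pair; four within-domain
  pairs) in the two smaller cohorts;
* global network–g effects of 0.18 (SC), 0.13 (FA), $-0.08$ (MD) — the
  reported medians for those weightings — with age moderation $+0.017$
  (FA) and $-0.045$ (MD) per SD of age and none for SC;
* an SC–total-brain-volume correlation target of 0.80, built by
  construction from the participant's total streamline count;
* FA decreasing and MD increasing with age (−0.015 / +0.025 per SD of
  age in their own units).

Networks come from a distance-dependent template over deterministic
pseudo-anatomical coordinates: edge presence is Bernoulli with
cohort-perturbed, density-recalibrated probabilities; SC weights are
log-normal around a distance-decaying mean; participant-level g-drivers
$t = \beta g + \sqrt{1-\beta^2}\,e$ multiply the weights (so the realised
metric–g correlation matches the nominal effect — verified to within
about 0.01 by simulation). Edge-level effects are modelled as per-edge
*modulation* of the shared driver (sensitivity $1 + 0.5u_e$ with a fixed
standard-normal map $u_e$): effect sizes then vary across edges while
remaining largely redundant, which keeps composite-prediction
correlations in the realistic 0.1–0.3 range instead of compounding
hundreds of independent signals into near-perfect prediction. A sparse
`beta_edge_map` adds independent targeted edge effects for recovery
experiments. Missingness is MCAR — the simplest case under which FIML is
valid.

What the generator does **not** emulate: tractography geometry, voxel
data, realistic anatomical distances, site-specific test batteries,
selective (MAR/MNAR) missingness, or non-linear age effects. Passing
tests therefore demonstrate the correctness and calibration of the
*statistical machinery* under the stated conditions, not performance on
real cohort data.

All randomness flows from a single root seed, expanded per cohort/stage
by a deterministic hash; identical seeds give bit-identical cohorts and
pipeline outputs (tested via file checksums).

# Numerical choices and degenerate inputs

* Asymmetry tolerance on load: $10^{-9}$ absolute; within it, matrices
  are symmetrised from the upper triangle.
* `K = round(density * 3570)`; at 0.30 the rounding is exact (1071).
* Zero-variance metrics and edge columns become flagged rows / dropped
  columns with warnings, never silent failures; batch association never
  aborts on a single bad column.
* All-zero matrices: efficiency and clustering are 0 by definition.
* Collinear covariate blocks are rejected with the condition number.
* Percentages in classification tables are reported to one decimal
  (round-half-even), matching the reporting style of the field.
* Output tables serialise floats at 10 significant digits.

# Problem sizes

The default pipeline run uses 800/400/300 participants and the test
suite uses cohorts of 60–2000 with a single 16 000-participant cohort
(masked edges only) for the hold-out stability check; these sizes give
Monte-Carlo error well inside every tolerance asserted while keeping a
full run to minutes on one core. The acceptance script mirrors them.

# Known limitations

* The FIML optimiser uses numerical gradients; for batteries much larger
  than ~15 tests an analytic-gradient implementation would be faster.
* SRMR under missingness uses listwise-complete moments and is reported
  `NA` when too few complete rows exist.
* The one-step SEM treats covariates as fixed regressors; standard
  errors condition on the observed covariate covariance.
* REML with three studies is inherently fragile; the flagged DL fallback
  makes this visible rather than solving it.
* Edge-level inference in the default pipeline uses the disattenuated
  two-stage estimator; the one-step SEM remains available per metric.
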