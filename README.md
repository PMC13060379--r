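# netcog

Structural brain networks and general cognitive function (*g*): a tested,
reusable implementation of the full analysis chain used in large
multi-cohort connectome studies — for network-neuroscience and
biostatistics researchers who want to run, audit, or extend this kind of
analysis without access to restricted cohort data.

## What it does

Given per-participant 85×85 connectivity matrices in three weightings
(streamline count SC, fractional anisotropy FA, mean diffusivity MD),
cognitive test scores with missing entries, and covariates (age, sex,
site), the package:

1. builds a cross-cohort **reference network**: consistency thresholding
   (lowest coefficient of variation of SC weight across participants) to
   a target density per cohort — 30% density keeps exactly 1071 of the
   3570 node pairs — then intersection of the cohort masks;
2. computes **weighted graph metrics** on the masked networks: mean edge
   weight, global efficiency
   `E = mean over pairs of 1/d_ij` (lengths `1/w`), Onnela mean
   clustering, and nodal local efficiency;
3. estimates latent ***g*** by one-factor confirmatory factor analysis
   with a **FIML** estimator (casewise likelihood over each participant's
   observed-test pattern; latent variance fixed to 1) and reports CFI,
   TLI, RMSEA, SRMR;
4. fits **structural regressions** of *g* on each metric (one-step MIMIC
   SEM; standardised β, Wald CI, p), adjusting for age, sex and site,
   with optional age × metric moderation per SD of age;
5. pools the three cohorts by **random-effects meta-analysis** (REML τ²,
   DerSimonian–Laird fallback flagged) with **Benjamini–Hochberg FDR**
   per weighting × scale family;
6. evaluates **edge-wise composite prediction** of *g*
   (`score = Σ β_k · z_k` over the reference edges) in an untouched
   hold-out half, plus cross-cohort agreement, hemispheric symmetry and
   hemisphere/lobe edge classification.

A synthetic multi-cohort generator (`sim_config()`, `simulate_cohorts()`)
reproduces the statistical structure the analysis assumes — three cohorts
with distinct sizes, age ranges, sites, densities; loadings spanning
0.28–0.73; network–g effects of 0.18/0.13/−0.08 for SC/FA/MD; an SC–brain
volume correlation of 0.80 — so the entire chain runs end-to-end with no
data download.

## Worked example

```r
library(netcog)
cfg <- sim_config(seed = 42)
cfg$cohorts$cohort_b$n <- 300
co <- simulate_cohort(cfg, "cohort_b")

mask <- consistency_threshold(co$networks$SC, density = 0.30)
mask
#> Edge mask: 1071 edges over 85 nodes (density 0.300)
#> Provenance: consistency threshold, density 0.3, K=1071

met <- network_metrics(co$networks$SC, mask, weighting = "SC")
fit <- gcfa(co$tests, rescov = co$rescov)
fit
#> One-factor g model (FIML), n = 300
#> Converged: TRUE  logLik: -1785.886
#> Standardized loadings:
#> test01 test02 test03 test04 test05
#>  0.397  0.403  0.576  0.771  0.840
#> Fit: CFI 0.999  TLI 0.996  RMSEA 0.018  SRMR 0.041

netg_assoc(met$global$global_efficiency, co$tests, co$covars,
           estimator = "sem", metric_id = "SC_global_efficiency")
#>              metric_id      beta         se      ci_lo     ci_hi           p
#> 1 SC_global_efficiency 0.1995443 0.06261184 0.07682509 0.3222635 0.001437539

meta_pool(c(0.21, 0.16, 0.12), c(0.03, 0.06, 0.08))
#>   beta_meta    se_meta            p tau2 estimator
#> 1 0.1919101 0.02543995 4.569911e-14    0      REML
```

The mask holds the 1071 most consistent connections (exactly 30% of all
pairs). The CFA recovers moderate-to-high standardized loadings with an
excellent fit (the battery is generated from a true one-factor model).
The structural regression says one SD of SC global efficiency predicts
about 0.20 SD of latent *g* after adjusting for age, sex and site —
matching the injected effect — and the pooled coefficient combines three
cohort estimates with no between-cohort heterogeneity (τ² = 0).

The whole chain, end to end:

```r
cfg <- run_config(seed = 1)          # 800/400/300 participants
run_pipeline(cfg, "runs/exp1")       # writes CSVs + manifest.json
```

A thin command-line wrapper lives at `inst/cli/netcog.R`
(`Rscript netcog.R run --seed 1 --out runs/exp1`).

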