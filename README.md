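# twincrp

Genetically sensitive twin-cohort analysis of childhood victimization and
C-reactive protein (CRP).

## What this package is for

Victimized children show elevated inflammation biomarkers in adulthood, but
CRP is moderately heritable and genetic liability may itself raise the risk
of being victimized. A same-sex twin design can separate these stories, and
`twincrp` implements that analysis end to end for biostatisticians and
epidemiologists working with family-clustered biomarker data:

* **Synthetic twin cohorts** (`default_study_preset()`, `generate_cohort()`):
  seeded cohorts of MZ/DZ same-sex pairs whose composite latent log-CRP has
  unit variance and within-pair covariances `A + C` (MZ) and `A/2 + C` (DZ),
  calibrated so the preset reproduces the published twin correlations
  `rMZ = 0.56`, `rDZ = 0.33` (hence `A = 0.46, C = 0.10, E = 0.44`), the
  published victimization-count distribution, sex-specific exposure effects,
  blood-spot assay noise (CV 3.3%) and an acute-inflammation contamination
  tail above 10 mg/L.
* **CRP preprocessing** (`dbs_to_serum()`, `apply_exclusions()`,
  `winsorize_victimization()`, `derive_analysis_variables()`): the
  blood-spot calibration `serum = 6.51 * bloodspot + 0.14` mg/L, the strict
  `> 10` mg/L acute exclusion with reconciled counts, the 0/1/2+ exposure
  winsorization, the natural-log transform, the top-tertile high-CRP flag
  and sample-mean imputation of covariates.
* **Twin models** (`within_pair_correlations()`, `fit_ace()`, `falconer()`,
  `latent_genetic_score()`): double-entry within-pair correlations,
  maximum-likelihood ACE decomposition with profile-likelihood CI for the
  heritability fraction

  `a = 2(rMZ − rDZ), c = 2 rDZ − rMZ, e = 1 − rMZ` (Falconer oracle),

  and the 4-level co-twin latent genetic risk score
  (MZ/no = 0 < DZ/no = 1 < DZ/yes = 2 < MZ/yes = 3).
* **GEE regression** (`build_model_design()`, `fit_gee()`): a from-scratch
  linear generalized-estimating-equations estimator with exchangeable
  working correlation, clustered on family, cluster-robust sandwich
  standard errors, and the Baseline/Model 1–4 covariate ladder
  (exposure → + genetic score → + SES → + waist–hip ratio and body
  temperature → all).
* **Pipeline** (`run_pipeline()`, `table1_report()`): the four-step sequence
  (exposure association, sex stratification, genetic decomposition,
  covariate-adjusted ladder) from a single config, with deterministic seeded
  reports, broom-style `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(twincrp)

cfg <- pipeline_config(
  spec = default_study_preset(n_families = 5000, seed = 42),
  strata = "F"
)
report <- run_pipeline(cfg)
report
```

Output (abridged):

```
<exclusion_report> 312 of 10000 excluded (serum CRP > 10 mg/L); N = 9688 retained

within-pair correlations (log-CRP):
  zygosity n_pairs     r
1 MZ          2585 0.561
2 DZ          2107 0.350

<crp_ace> univariate twin-model variance decomposition
  A = 0.418 [profile 95% CI 0.334, 0.503]   C = 0.142   E = 0.440

latent-score validation:
      n beta_level      se  p_value beta_std r_squared stratum
1  9384      0.328  0.0108  6.3e-203   0.364     0.135 all

linear victimization trend (b, robust SE, p) by stratum:
  all b =  0.174 (SE 0.017), 95% CI 0.142; 0.206, p = 6.71e-26
  F   b =  0.285 (SE 0.023), 95% CI 0.239; 0.330, p = 2.23e-34
  M   b =  0.064 (SE 0.022), 95% CI 0.021; 0.107, p = 0.00386
```

Reading this: the twin correlations land on the calibrated 0.56/0.33
structure, so about 42% of log-CRP variance is attributed to additive
genetics in this draw (true value 0.46, inside the profile CI). The latent
genetic score explains ~13% of CRP variance. The victimization trend on
log-CRP is concentrated in females (b ≈ 0.28 per exposure category vs
0.06 in males), and `report$table1$F` renders the Baseline/Model 1–4 ladder
showing the poly-victimization coefficient surviving adjustment for the
genetic score and the other covariates — the pattern the design is built to
probe.

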