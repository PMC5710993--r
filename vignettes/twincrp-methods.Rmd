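---
title: "Methods: genetically sensitive analysis of childhood victimization and CRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically sensitive analysis of childhood victimization and CRP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twincrp)
```

## The scientific problem

Children exposed to victimization (domestic violence, bullying, maltreatment,
abuse, neglect) show elevated levels of the inflammation biomarker C-reactive
protein (CRP) in adulthood. Two confounds complicate the causal reading of
that association in young people: CRP levels are moderately heritable, and
genetic liability may itself raise the risk of experiencing victimization
(gene--environment correlation). A same-sex twin design addresses this by
(i) quantifying the genetic contribution to CRP through the differing genetic
resemblance of monozygotic (MZ) and dizygotic (DZ) pairs, and (ii) adjusting
the exposure--outcome regression for a co-twin-based latent genetic risk
score.

`twincrp` implements that full analysis as a reusable, tested pipeline:
a calibrated synthetic twin-cohort generator, dried-blood-spot CRP
preprocessing, twin variance-component models, a from-scratch
generalized-estimating-equations (GEE) regression engine with cluster-robust
variance, and an orchestrator that reproduces the published model ladder.
Because no individual-level data are deposited for cohorts of this kind, the
generator is a first-class component: it creates cohorts with the published
statistical structure so that every downstream estimator can be validated by
parameter recovery.

## The synthetic cohort model

Each family contributes one same-sex twin pair. For pair member $j$ the
composite latent trait is

$$z_j = \sqrt{\tilde a}\,A_j + \sqrt{\tilde c}\,C + \sqrt{\tilde e}\,E_j
      + \frac{1}{\sigma}\left[\beta_{s}(k_j) + \beta_{\mathrm{SES}}
      + \beta_{\mathrm{whr}}(w_j - \mu_w) + \beta_{\mathrm{temp}}(t_j - \mu_t)\right],$$

with $A$ bivariate standard normal across the pair (correlation 1 for MZ,
0.5 for DZ), $C$ shared, $E_j$ independent, and all mean-shift effects
centered. Serum CRP is $\exp(\mu + \sigma z_j)$ mg/L; the stored blood-spot
value inverts the serum calibration $\mathrm{serum} = 6.51\,\mathrm{bs} + 0.14$
and carries multiplicative lognormal assay noise (CV 3.3%). A 3%
contamination fraction has serum resampled from an acute-inflammation
distribution strictly above 10 mg/L, exercising the exclusion rule.

### Calibration of the variance components

The preset ACE fractions $(A, C, E) = (0.46, 0.10, 0.44)$ are the unique
solution of $r_{MZ} = A + C = 0.56$ and $r_{DZ} = A/2 + C = 0.33$, the
published within-pair correlations. Those correlations describe *measured*
CRP, i.e. the composite trait including exposure, SES and covariate
contributions -- not a bare ACE kernel. The generator therefore solves for
raw components

$$\tilde a = A, \qquad \tilde c = C - S, \qquad \tilde e = E - U,$$

where $S$ and $U$ are the shared and unique variance contributed by the
mean-shift effects (closed form, computed from the spec). Family-level
victimization and SES effects are genuinely shared environment, so absorbing
them into the $C$ budget is the substantively correct accounting; individual
covariate noise is unique environment. The composite then has unit variance
and within-pair covariances $A + C$ (MZ) and $A/2 + C$ (DZ) *exactly*, so
twin correlations, heritability recovery and the latent-score validity all
refer to one coherent trait. A specification whose effects exceed the $C$ or
$E$ budget ($S > C$ or $U > E$) is rejected with a configuration error
rather than silently rescaled.

### Choice of the serum scale

`serum_mu = log(0.6)` puts the median serum-equivalent CRP at 0.6 mg/L,
typical of late adolescence. The scale `serum_sigma = 0.8` was fixed by two
physical constraints of the blood-spot assay rather than by fit: the
conversion line has intercept 0.14 mg/L, a hard floor for serum-equivalent
values, and values above 10 mg/L are excluded as acute inflammation. With
$\sigma = 0.8$ under 4% of healthy values fall at the conversion floor
(stored at the assay detection limit) and the healthy tail above 10 mg/L is
about 0.1%, so total exclusions sit near the 3% contamination rate --
matching the roughly 3.2% of records the published analysis excluded. A
wider scale would censor appreciably more of the lower tail and inflate the
exclusion fraction. Consequently, all effect sizes in the spec are stated on
the log serum scale (the scale of published regression coefficients) and are
divided by $\sigma$ when entering the standardized latent trait; the GEE on
log serum-equivalent CRP then recovers them directly.

### Exposure and effect parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| `exposure_probs` | (73.5, 20.1, 3.8, 1.8, 0.8, 0.1)% / 1.001 | published 0--5 type frequencies, rescaled to unit sum (the printed values total 100.1% from rounding) |
| `exposure_concordance` | 1 | victimization types here (domestic violence, neglect) are largely household-level; both twins share the family count. No within-pair concordance is published, so this is an assumption; the parameter allows sensitivity analyses in $[0,1]$ |
| `effect_female` | (0, 0.21, 0.56) | published female category coefficients, log-CRP units |
| `effect_male` | (0, 0.10, 0.20) | only the male linear trend (0.10/category) is published; this encoding makes the fitted linear slope exactly 0.10 |
| `ses_effect` | (0.28, 0.09, 0) low/middle/high | published baseline signs and magnitudes; generative truth is otherwise free |
| `covariate_params` | WHR 0.80 (SD 0.06), $\beta$ = 3.82; temperature 36.8 °C (SD 0.4), $\beta$ = 0.19 | realistic age-18 moments; $\beta$s use published baseline magnitudes |
| `measurement_cv` | 0.033 | blood-spot assay duplicate CV |
| `contamination_rate` | 0.03 | acute-phase fraction, resampled above 10 mg/L |
| `missing_rates` | 25/888, 7/888 | published missing counts for WHR and temperature |

Within-pair covariate resemblance is modeled as a zygosity-independent
household component (`rho` = 0.4 for waist--hip ratio, 0.2 for temperature).
A heritable (zygosity-dependent) WHR share would be more realistic but is
infeasible under the preset: its shared part would push $S$ past the
$C = 0.10$ budget. This is a documented simplification.

## Preprocessing rules

* Conversion is the affine calibration; negative blood-spot input is a
  domain error.
* The acute exclusion is strict (`serum > 10`), matching the published rule;
  the report reconciles `n_input = n_excluded + n_retained` exactly.
* Winsorization maps counts 0/1/2+ to `none`/`one`/`poly` and is idempotent.
* The log transform is the natural log (configurable base): the published
  analysis says only "log-transformed".
* The high-CRP flag is the top tertile of the *post-exclusion* serum
  distribution, pooled across sexes. Whether the original study cut the
  tertile before or after the exclusion is not stated; post-exclusion is the
  reproducible choice here and is computed rank-based with ties broken by
  stable record order (later records rank higher), flagging exactly
  $\lceil n/3 \rceil$ records.
* Missing waist--hip ratio and temperature are replaced by the sample-wide
  mean of observed values on the post-exclusion sample; an all-missing
  column is an error.

## Twin models

Within-pair correlations use the double-entry estimator (each pair entered
in both orders), which is invariant to the arbitrary twin labelling; the
published estimator is not stated.

`fit_ace()` maximizes the bivariate-normal likelihood over pairs with a
common mean and total variance and expected within-pair covariance
$\sigma^2_A + \sigma^2_C$ (MZ) or $\sigma^2_A/2 + \sigma^2_C$ (DZ).
The likelihood is evaluated from per-group sufficient statistics, so a fit
on 50,000 pairs takes well under a second. Variance components are
parameterized directly with non-negativity bounds (not via a Cholesky
factor): boundary solutions (e.g. $\hat A = 0$ when $r_{MZ} \le r_{DZ}$) are
then interpretable and the profile-likelihood interval for the heritability
fraction is straightforward (inner re-maximization over mean, total variance
and the C share, bracketing the $\chi^2_1$ cutoff). A family-level bootstrap
CI is available as an alternative. The Falconer closed form
$a = 2(r_{MZ} - r_{DZ})$, $c = 2 r_{DZ} - r_{MZ}$, $e = 1 - r_{MZ}$ serves
as the independent oracle in the tests, never as the fitting routine.

The latent genetic risk score codes (zygosity, co-twin high-CRP) as
MZ/no = 0, DZ/no = 1, DZ/yes = 2, MZ/yes = 3. Records whose co-twin was
excluded cannot be scored; they are dropped from score-based models with a
reported count, never imputed. The score enters models as a single
continuous 0--3 regressor (the published report of one beta with an
$R^2$ implies continuous coding); `score_validation()` reports both
published-beta conventions -- the GEE-weighted standardized slope and the
plain score/trait correlation $\sqrt{R^2}$ -- because the two differ
slightly under family clustering, which plausibly explains why the published
beta (0.33) and $R^2$ (13%) are not linked by $\beta^2 = R^2$.

## The GEE engine

`fit_gee()` is a from-scratch linear (identity link, Gaussian variance) GEE
with exchangeable working correlation, clustered on family:

1. initialize coefficients by least squares;
2. moment-update the exchangeable $\rho$ from standardized residual
   cross-products with the small-sample denominator correction
   (subtracting the number of regression parameters);
3. solve the weighted estimating equations using the closed-form inverse of
   the exchangeable correlation (cluster-sum algebra, no per-cluster matrix
   inversions);
4. iterate to a coefficient-change tolerance of 1e-8 (default budget 100
   iterations; exceeding it flags the fit rather than passing silently).

$\rho$ is clamped to the positive-definite region, with an upper cap of
0.995 so cluster-constant designs (where the estimate is invariant to
$\rho$) remain numerically stable. Robust variance is the cluster sandwich
(per-cluster score outer products); the model-based variance is also kept,
and for singleton clusters both the coefficients and the model-based
variance reduce exactly to ordinary least squares. Confidence intervals are
normal-approximation $\pm 1.96\,\mathrm{SE}$, matching the published
reporting style; no multiple-testing adjustment is applied, mirroring the
original analysis.

The model ladder fits exposure alone (baseline), then adds the latent
genetic score (model 1), SES tertiles (model 2), waist--hip ratio and body
temperature (model 3), and everything simultaneously (model 4), with
exposure entered either as two dummies against `none` or as the 0/1/2
linear trend -- both codings are available because published reports quote
both. The exposure-by-sex interaction is a robust Wald test of the product
term in the pooled linear-trend model.

## What the generator does and does not emulate

It reproduces: the MZ/DZ and sex composition, the victimization-count
distribution, twin correlations of the composite trait, sex-specific
exposure effects, blood-spot assay noise, the acute contamination tail, and
covariate missingness. It does not attempt: longitudinal CRP trajectories,
item-level victimization dossiers, exposure--covariate confounding (SES,
adiposity and exposure are generated independently, so ladder adjustments
barely move the exposure coefficient here, unlike in real data where such
confounding is the point of adjusting), non-normal latent tails, or
zygosity-dependent covariate resemblance. Passing recovery tests therefore
demonstrates estimator correctness under the stated model, not robustness
to every feature of real cohort data.

## Numerical choices and problem sizes

Large-sample checks (twin correlations, heritability recovery, effect
recovery, score validity) use 50,000-family cohorts, where Monte-Carlo
error is comfortably inside the stated bands (correlations ±0.02, effects
±0.05, $R^2$ ±1.5 points); distributional and property checks use
2,000--20,000 families; bootstrap comparisons use 200 families with a few
hundred replicates. Expected small attenuations are documented rather than
hidden: the conversion floor left-censors about 3% of healthy values and
the >10 mg/L rule truncates slightly more exposed than unexposed
individuals, together depressing the recovered female poly-victimization
coefficient by roughly 0.02 relative to the injected 0.56.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  spec = default_study_preset(n_families = 5000, seed = 42),
  strata = "F"
)
report <- run_pipeline(cfg)
report$correlations    # rMZ ~ 0.56, rDZ ~ 0.33
tidy(report$ace)       # A/C/E fractions with profile CI on A
report$score_validation
report$table1$F        # Baseline + Models 1-4, published layout
autoplot(report$ladder_fits$F$baseline)
```

## Known limitations

* The exchangeable working correlation and independence are the only
  working structures; for twin data they are the natural choices.
* The ACE model is univariate; no sex-limitation, bivariate or longitudinal
  extensions, and no DNA-based polygenic scores.
* The blood-spot conversion is taken as fixed; the paired-sample calibration
  data needed to refit it are not public.
* Mean imputation of covariates follows the published analysis; it
  understates covariate uncertainty by construction.
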