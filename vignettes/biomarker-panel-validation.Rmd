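---
title: "Validating a multi-pathway biomarker panel for eGFR decline: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a multi-pathway biomarker panel for eGFR decline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In type 2 diabetes, kidney function — summarized as the estimated glomerular
filtration rate (eGFR) — declines at very different rates across patients.
Established risk markers (albuminuria, blood pressure, smoking, baseline
eGFR, ...) explain part of that heterogeneity. The question this package
addresses is whether a panel of circulating biomarkers drawn from several
disease pathways (inflammation, fibrosis, angiogenesis, endothelial
function, mineral and lipid metabolism, glomerular damage) adds predictive
value for the *annual eGFR slope* beyond those established markers, in a
small cohort (n = 82) with roughly annual creatinine measurements over about
four years.

Because small-sample prediction studies are prone to optimism, the package
implements the complete validation machinery — penalized selection,
internal bootstrap validation, a global added-value test — together with a
synthetic cohort generator that reproduces the cohort's marginal structure,
so every stage can be tested end to end without access to patient data.

## Outcome construction

Each serum creatinine measurement (µmol/L) is converted to eGFR with the
4-variable MDRD study equation,

$$\mathrm{eGFR} = C \cdot (\mathrm{Scr}/88.4)^{-1.154} \cdot
\mathrm{age}^{-0.203} \cdot 0.742^{\,\mathrm{female}} \cdot
1.212^{\,\mathrm{black}},$$

with $C = 175$ (IDMS-traceable re-expression) by default; $C$ is a
configuration field because the original 186 calibration is still in use.
The per-patient outcome is the ordinary-least-squares slope of eGFR on time
in years, requiring at least three measurements; patients with fewer are
excluded with a logged reason. *Accelerated decline* is a slope strictly
below −3 mL/min/1.73m²/year.

Two conventions matter and are both supported:

* **Age at follow-up visits.** By default age is held at its baseline value
  when evaluating the MDRD equation, so ageing is absorbed into the slope.
  Setting `advance_age = TRUE` advances age per visit; the synthetic
  round-trip tests use this, because the generator inverts the equation
  with age advanced.
* **Units.** Creatinine enters in µmol/L and is divided by 88.4 internally.
  UACR is carried in mg/mmol; multiplying by 8.84 converts to mg/g for
  display.

## Preprocessing

Following the study's rules: biomarkers with more than 10% missing values
or more than 25% of values below the assay limit of detection (LOD) are
excluded (strict inequalities — exactly 10%/25% is retained); values below
the LOD are set to the LOD; UACR is natural-log transformed and every
biomarker binary-log transformed, so regression coefficients read *per
doubling of concentration*. On the default synthetic panel this reproduces
the 28 → 23 reduction deterministically.

Remaining missingness is multiply imputed by chained equations, authored in
the package: missing cells are initialized from observed marginals, then
each incomplete variable is regressed on all others for a fixed number of
cycles — Bayesian linear regression with predictive-mean matching (donor
pool k = 5) for continuous variables, a logistic posterior draw for
binaries, falling back to an observed-marginal draw with a warning if the
logistic fit degenerates. Defaults m = 10 imputations, 10 cycles; these are
ordinary chained-equations defaults and are configuration fields, since the
source analysis does not state its values. The downstream pipeline runs
once per completed dataset; scalar metrics (R², C-index, ΔR², global p) are
pooled by arithmetic mean and the non-penalized association models by
Rubin's rules. Rubin's variance combination is *not* applied to LASSO
coefficients (it is not congenial for penalized estimators); per-imputation
results are retained instead.

## Penalized selection

The model engine is an L1-penalized linear regression solved by cyclic
coordinate descent on standardized predictors (mean 0, unit population SD;
intercept unpenalized), minimizing

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i'\beta)^2 + \lambda \|\beta\|_1 ,$$

with warm starts along a 100-point log-spaced grid from $\lambda_{\max}$
(smallest penalty with an all-null model) down to $10^{-3}\lambda_{\max}$.
Convergence requires the largest standardized coefficient change in a sweep
to fall below $10^{-7}$ (cap $10^5$ sweeps); solutions satisfy the KKT
conditions to ~$10^{-9}$ in the test suite and match an independent solver
to ~$10^{-8}$ along the whole path. Binary predictors are standardized like
continuous ones, matching the default of the standard software for this
model family. The solver works on sufficient statistics (Gram matrices
with rank-one downdates per fold), which is what makes the nested
resampling affordable.

The penalty is tuned by **leave-one-out cross-validation**: the full path
is refit on each n−1 subset (re-standardizing within the fold; a predictor
degenerate within a fold is dropped for that fold), and the chosen
$\lambda$ minimizes the CV mean squared error — the minimum-CV rule, not
the 1-SE rule, because the source analysis selects the model with the best
cross-validated MSE. Exact ties go to the larger penalty (sparser model).
Coefficients whose standardized magnitude falls below the convergence
tolerance are treated as zero when reporting the active set; this only
matters for degeneracies such as duplicated columns, where at most one of
the pair can meaningfully be active.

The modeling sequence mirrors the study: (1) LASSO selection among the
established risk markers defines the *reference* set; (2) univariate and
(3) reference-adjusted OLS models per biomarker; (4) one LASSO over
reference markers plus all retained biomarkers defines the *optimal*
combined model.

## Bootstrap validation and the added-value test

Validation is the *simple bootstrap*: for b = 1…B (default 1000), resample
patients with replacement, rerun the entire selection (including the
leave-one-out penalty tuning *inside* the resample — with duplicated rows
this is leave-one-copy-out), and apply the fitted model to the original
data unchanged. From the B models:

* **Bagged prediction / R².** Each patient's prediction is averaged over
  resamples; the model MSE is the mean squared difference between observed
  outcome and bagged prediction, and $R^2 = 1 - \mathrm{MSE}/\mathrm{var}(y)$
  (variance with denominator n, fixed for bit-reproducibility; R² can be
  negative). The alternative reading — average over resamples of each
  resample-model's MSE — is available behind
  `validation_config(mse_aggregation = "per_resample")`.
* **C-index.** Observed outcomes are dichotomized at −3; the risk score is
  the negative bagged predicted slope. The C-index is the fraction of
  (accelerated, non-accelerated) pairs ranked correctly, ties 0.5 —
  computed via midranks and invariant to any monotone calibration of the
  score, which is why no explicit probability mapping is needed. If only
  one class is present it is reported as NA.
* **Coefficient inference.** Per variable: mean coefficient over draws
  (zero when unselected), percentile 95% CI from the 2.5th/97.5th empirical
  percentiles (type-7 quantiles — CI endpoints depend on the percentile
  rule, so it is fixed and stated), a two-sided percentile p-value
  $2\min(\Pr(\hat\beta \le 0), \Pr(\hat\beta \ge 0))$ clipped to [2/B, 1],
  and the selection probability (fraction of resamples with a nonzero
  coefficient).
* **Global added-value p.** Reference and full models are validated on the
  *same* resample sequence; the p-value is the fraction of resamples in
  which the full model's tuned CV-MSE is greater than or equal to the
  reference model's, floored at 1/B. Ties count against the richer model —
  the conservative direction.

The omit-one sensitivity analysis removes each optimal-model variable from
the candidate pool in turn and reruns selection, reporting recruited
replacements.

**Known property: in-sample optimism.** Because resample fits are evaluated
on the original data, bagged R² is optimistic: under a pure-noise outcome
(n = 60, p = 10) it averages ≈ 0.15 rather than 0. An independent engine
(the reference CV-LASSO implementation inside the identical resampling
loop) reproduces this package's values to ~10⁻⁶, so the optimism belongs to
the procedure, not the solver. This is the same limitation that motivates
external validation of the original analysis; the global p-value, which
compares the two models *within* resamples, is calibrated (null rejection
≈ 2–5% at α = 0.05 in the test suite). Relatedly, the min-CV tuning rule
admits null predictors into roughly half the resample models, so selection
probabilities near 0.5 are uninformative baseline, not evidence — only
values well above it (the study reports 0.74–0.999 for its selected
variables) separate from noise.

## The synthetic cohort generator

The generator is the package's study stand-in; it emulates:

* **Clinical covariates** as truncated Gaussians at the cohort's means/SDs
  (truncation bounds from plausibility and the 35–75 eligibility window),
  with the pre-truncation location moment-matched so the *truncated* mean
  equals the target — naive truncation would bias age ~2 years low.
  Binary covariates are Bernoulli at the reported proportions.
* **UACR and the 28 biomarkers** as two-piece log-normals centred at the
  printed median with separate lower/upper log-scale SDs matching the
  printed quartiles exactly. A single symmetric log-normal cannot do this:
  the printed quartiles are strongly asymmetric on the log scale (e.g.
  TNFR1 3.8 [3.1, 6.7]; UACR 1.2 [0.5, 57.7]). The symmetric
  quartile-matching spread $(\ln q_3 - \ln q_1)/(2\cdot 0.6745)$ remains
  available as a helper. Cross-marker dependence is a single latent factor
  per pathway (loading 0.5, i.e. within-pathway log-scale correlation
  0.25) — the pathway grouping is stated but no correlation values are,
  and a full correlation matrix can be supplied; specs failing positive
  semidefiniteness (smallest eigenvalue < −10⁻⁸) are rejected. The five
  markers excluded by the original QC carry *synthetic* concentration
  scales (only their QC failure matters) and rates engineered to violate
  the bounds.
* **The outcome truth**: slope = intercept + Σ βⱼxⱼ + ε on transformed
  predictors, with default effects on ln-UACR, SBP, baseline eGFR, smoking,
  sex, oral medication and five biomarkers (TNFR1, MMP7, MMP2, CTGF, TEK)
  at magnitudes in the range of the reported multivariable coefficients.
  The intercept is computed in closed form so the expected slope is −2.1
  mL/min/1.73m²/yr, and the residual SD (2.55) is calibrated so the
  marginal slope SD is ≈ 4.5 — the reported Results-section moments (the
  abstract's −2.0 ± 4.7 is recorded here for completeness; the generator
  targets the Results values). At n = 5000 the realized moments are within
  a few percent.
* **Creatinine series** by exact algebraic inversion of the MDRD equation
  along eGFR(t) = baseline + slope·t (age advanced by t), times mean-1
  log-normal measurement noise with CV 0.05 (a typical assay CV). The
  noiseless round trip recovers the input slope to 10⁻⁶. Patients whose
  latent trajectory would cross 1 mL/min/1.73m² within follow-up (~1% of
  draws) have the slope clamped at the boundary; the recorded truth is the
  clamped slope. Visit schedule: {0, 1, 2, 3, 4} years (annual visits).
* **Missingness and censoring** as exact-count MCAR masking
  (`round(rate·n)` cells at random positions) and below-LOD flags topped up
  to `round(rate·n)` among non-missing cells; exact counts make the QC
  decision deterministic at any seed while positions stay random. Default
  LODs sit at the rate-quantile of each marker's marginal (median/50 when
  the rate is zero).
* **Seed discipline**: a master seed spawns named substreams (clinical /
  biomarker / outcome / creatinine / missingness / imputation /
  bootstrap), so changing one stage's parameters does not shift another
  stage's draws; everything is bit-reproducible given the configuration.

What the generator does **not** emulate: assay plate effects and storage
degradation, visit-time jitter and dropout, non-linear or time-varying
slope structure, and real between-pathway correlation. Passing tests
therefore demonstrate that the *machinery* is correct and calibrated under
the stated data model, not that the biological conclusions transfer.
Because age is held at baseline in the default outcome construction while
the generator ages patients, measured mean decline sits ~0.2 units above
the latent truth — the ageing term of the MDRD equation absorbed into the
level rather than the slope; `advance_age = TRUE` removes the gap.

## Problem sizes and numerical choices in the test suite

The suite exercises the engine at the study's scale where that matters
(82 patients and hence 82 CV folds; 28 → 23 markers; B in the hundreds)
and at reduced scale elsewhere: solver optimality against a sign-pattern
enumeration oracle at n ≤ 12, p ≤ 6; null calibration of the global p at
n = 60, p = 5 + 10, B = 100 over 50 replicates; ΔR² recovery at n = 82,
B = 200 over 20 replicates on a design with population R² 0.377 → 0.546;
selection probabilities at n = 82, p = 23, B = 200. The acceptance script
runs the full pipeline at n = 82 with m = 5 imputations and B = 400. These
sizes are the package's own choices to keep the checks sharp and the
default run brisk; B = 1000 and m = 10 (the analysis defaults) behave
identically, only more slowly.

## Known limitations

* The simple bootstrap's R²/C-index are optimism-inflated (see above);
  they validate *internal* stability, not transportability.
* Percentile CIs for LASSO coefficients mix shrinkage and selection; their
  coverage is not nominal and they are reported as the study reports them,
  descriptively.
* The chained-equations imputer assumes roughly linear/logistic
  conditional models; with the panel's heavy-tailed markers the log2
  transform is doing real work there.
* Smoking is coded current vs not-current (former smokers pooled with
  never), the default reading of "current vs. never"; the coding is a
  configuration choice of the cohort builder.
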