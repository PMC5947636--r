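---
title: "Marginal structural modelling of cyclophosphamide efficacy in juvenile dermatomyositis"
author: "cycmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural modelling of cyclophosphamide efficacy in juvenile dermatomyositis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycmsm)
```

## The estimation problem

Cyclophosphamide (CYC) is a second-line treatment for severe juvenile
dermatomyositis.  Because randomized trials are infeasible in a disease
this rare, efficacy must be estimated from registry cohorts — and there
the treatment decision is confounded by indication: the sickest children
are the ones who receive CYC, and they also have the worst outcomes.  A
naive comparison of treated versus untreated patient-visits is therefore
biased *against* the drug, and the confounder (disease severity) varies
over time.

`cycmsm` implements the standard remedy for time-varying confounding, a
marginal structural model (MSM) estimated by inverse
probability-of-treatment weighting (IPTW).  Each patient-visit is
weighted by the inverse of the (cumulative) probability of the treatment
history that patient actually had, given their recorded covariate
history.  In the re-weighted pseudo-population, treatment assignment is
unrelated to the recorded confounders, so a simple weighted regression of
the outcome on treatment recency estimates the causal effect.

Disease activity is measured on three instruments: the modified skin
Disease Activity Score (DAS, 0-5, higher worse), the physician's global
assessment (PGA, 0-10, higher worse), and the Childhood Myositis
Assessment Scale (CMAS, 0-52, *lower* worse).

## Pipeline structure

`run_msm()` orchestrates five stages, each exposed as its own function:

1. **Eligibility** (`apply_eligibility`): retain incident cases — first
   recorded visit within 3 months of diagnosis, and a known CYC start
   date for anyone who ever received the drug.
2. **Multiple imputation** (`impute_cohort`): PGA and CMAS are missing at
   some visits (the skin score never is).  Five completed data sets are
   drawn by chained equations, and *every* later stage runs once per set,
   with Rubin pooling at the very end.  The conditional models carry the
   analysis model's own covariates — in particular the split-time
   treatment-recency factor, not just an on-treatment flag.  This
   congeniality matters: an imputation model blind to treatment recency
   imputes post-course scores toward the untreated mean and attenuates
   exactly the contrast being estimated (in calibration runs the
   attenuation reached ~17% of the planted PGA effect).
3. **Probability-of-treatment model** (`fit_potm`): three discrete-time
   logistic sub-models on the visit grid — receipt at the first visit,
   initiation given no prior CYC, and discontinuation given currently on
   CYC — with cluster-robust standard errors.
4. **Weights** (`compute_weights`, `truncate_weights`): stabilized
   ratio weights, truncated at 20.
5. **Outcome models** (`fit_weighted_outcome`, `pool_rubin`): weighted
   identity-link regressions of each score on time since diagnosis and a
   four-level treatment-recency ("split time") factor: never/not yet,
   course started within 6 months, 6-12 months ago, more than 12 months
   ago.  Because the treatment course itself lasts about half a year, the
   natural reading of the three contrasts is: still on treatment, course
   recently completed, course completed more than six months ago.

### Split-time coding

Category boundaries are half-open so the four levels partition the time
axis: exactly 6 months since the start date still counts as "within 6
months", exactly 12 as "6-12 months".  For any treated patient the
category is a non-decreasing step function of time; re-treatment (a
second course) is rejected at load time because the coding is undefined
for it.

### Probability-of-treatment model

The covariates of the initiation model are the current (imputed) scores,
time since diagnosis, age at diagnosis, and flags for the concomitant
medications most imbalanced between the treatment groups (intravenous
glucocorticoids, intravenous immunoglobulin, biologics).  The baseline
model uses the same set without time.  Discontinuation is dominated by
the treatment protocol — a noncontinuous course completed within about 6
months — so stopping is nearly deterministic in time-on-treatment; when
the logistic fit quasi-separates, the sub-model falls back automatically
to a banded empirical hazard with Agresti smoothing `(events + 0.5) /
(n + 1)`, which keeps every probability strictly inside (0, 1)
(positivity).  Separation elsewhere triggers a covariate-reduction
cascade that is recorded in the fit's `note`.

A fitted probability is only a positivity problem when the *observed*
state is given numerically zero mass; a tiny initiation probability at a
late visit where no initiation happened is legitimate (its observed-state
probability is near 1) and must not be mistaken for separation.

Denominator probabilities are **cross-fitted** by default
(`crossfit_folds = 5`): each patient's baseline and initiation
probabilities come from sub-models fitted with that patient's fold held
out.  In-sample propensity predictions overfit — the model partly
"explains" each patient's own treatment surprise, which shrinks the
weights of exactly the informative patients and leaves residual
confounding (+0.03-0.04 outcome units in 60-replicate calibration runs,
scaling with each outcome's severity loading; cross-fitting removes it).
The covariate-free discontinuation model and the low-dimensional
stabilizer numerators are fitted on the full risk sets.

An optional missing-indicator mode (`run_msm(potm_missing_indicators =
TRUE)`) adds imputed-cell flags and score-by-flag interactions to the
denominator sub-models, the classic remedy when single-draw imputed
covariates inject errors-in-variables noise into a propensity model.  It
is off by default: in 60-100-replicate calibration runs the extra
parameters (on ~35-55 initiation events) cost more bias than the
errors-in-variables correction recovered.

### Weights

Stabilized weights use numerator sub-models of the same structure with
baseline covariates only (age, sex); the discontinuation numerator keeps
the time-on-treatment bands, since treatment history may enter a
stabilizer.  After a completed course the treatment history is
deterministic and contributes a factor of exactly 1.  The default
truncation point of 20 follows common practice; it is configurable, and
on well-specified synthetic cohorts the cap never binds (stabilized
weights stay below ~10).

### Outcome model and pooling

The weighted outcome fit uses an independence working correlation (the
requirement for valid MSM point estimation with IPTW) with
cluster-by-patient sandwich variance.  The variance flavour interacts
with how the weights are predicted, and both were calibrated in
100-replicate runs: with *in-sample* weights the plain HC1 cluster
sandwich understates the Monte-Carlo sampling standard deviation by
15-25% (only the ~28% treated clusters identify the split-time
contrasts) and the bias-reduced HC3 form tracks it; with the default
*cross-fitted* weights the out-of-fold prediction noise already inflates
the estimated meat, HC3 then overcovers (all of 100 nominal-95%
intervals contained the truth), and HC1 is the calibrated choice
(coverage ~0.98; the residue of conservatism is the standard one from
ignoring weight estimation).  `fit_weighted_outcome(vcov_type=)` exposes
the choice.  Pooling follows Rubin's rules, `T = W + (1 + 1/m) B`, with
Barnard-Rubin small-sample degrees of freedom (complete-data df taken as
patients minus model rank).

## The synthetic cohort generator

No patient-level registry data are distributable, so validation rests on
`simulate_cohort()`, which generates cohorts with the structure the
analysis assumes:

* **Severity.** One latent scalar drives all three scores: patient set
  point `mu_i ~ N(0, 0.7^2)` plus a mean-reverting deviation (stationary
  SD 0.6, autocorrelation 0.85/month).  Observed scores are affine
  transforms with measurement noise (DAS = 3.2 + 0.8 S, noise SD 0.4;
  PGA = 5.2 + 1.8 S, SD 0.8; CMAS = 28 - 9 S, SD 3), clipped to their
  ranges.  The anchors place baseline medians near the registry's
  published values and keep range-clipping rare, so the planted additive
  effects are recoverable by a linear model.
* **Treatment.** At each visit an untreated patient starts CYC with
  probability logistic in a *recorded-severity composite* — a
  skin-dominant weighted mean of the three chart scores (weights
  0.5/0.25/0.25; ulcerative skin disease is the leading clinical
  indication for CYC, and the skin score is assessed at every visit) —
  plus a time decay of -0.5 log-odds/month, so initiations concentrate in
  the first weeks (median ~1 month after diagnosis).  Basing the decision
  on recorded chart scores, rather than on the latent severity, reflects
  how clinicians act and keeps the confounding capturable by the recorded
  covariates, so MSM assumptions hold by design.  The intercept is
  calibrated deterministically at configuration time so the expected
  treated fraction matches its target (default 28%).  Course length is
  lognormal (median 5.2 months, IQR ~4.6-6.5), truncated to 3-9 months;
  there are no discontinuers.
* **Effects.** Treatment enters as additive shifts of the observed
  scores per split-time category — matching the linear outcome model
  being validated — with defaults of -1.19 DAS and -0.66 PGA units for
  courses started more than 12 months ago and zero elsewhere.
* **Visits and follow-up.** Gamma renewal process, ~10 visits/year in
  year 1 and quarterly afterwards; per-patient follow-up uniform between
  2 years and ~13 years (mean 7.5 years).  The visit schedule is a
  modelling choice; registries do not publish theirs.
* **Missingness.** PGA ~25%, CMAS ~26% and glucocorticoid dose ~55% of
  cells, completely at random by default (a switch makes it
  severity-dependent for sensitivity work); DAS is never missing.  The
  registry may lose a score the clinician recorded on paper, so the
  indication composite uses all three chart values; the skin-dominant
  weighting keeps the part of the indication hidden by missingness small.

What the generator does *not* emulate: a systematic natural-history time
trend (severity is stationary around each set point, so the outcome
model's linear time term is genuinely null), informative loss to
follow-up, calcinosis/ulceration event processes beyond static flags, and
any pharmacokinetics.  Passing recovery tests therefore demonstrate that
the estimator chain is correct under its own assumptions — not that those
assumptions hold in any particular registry.

## Numerical choices and degenerate inputs

* Nominal-time alignment for the descriptive battery picks the visit
  minimizing distance to the nominal month within a +/-2-month window;
  equidistant ties go to the earlier visit, deterministically.
* Friedman blocks with all-tied values return statistic 0, p = 1 (the
  tie-corrected statistic is 0/0 there); complete-case blocks only.
* Signed-rank zeros are dropped before ranking; exact enumeration is
  used for small untied samples (<= 15 nonzero pairs; <= 10 combined for
  the rank-sum test), the tie-corrected normal approximation otherwise.
* Fisher's exact test is two-sided by the probability-mass method.
* The 2x2 chi-square uses Yates' continuity correction throughout: the
  published group-comparison p-values are reproduced with the correction
  and not without it.
* Imputation draws are clipped to the score ranges; each chain runs 10
  sweeps; a variable missing in every row is an error, as is pooling
  over a strict subset of imputations.
* All randomness flows from explicit integer seeds; child streams
  (replicates, imputation chains) use a deterministic integer hash of
  the master seed.

## Validation experiments and problem sizes

The test suite runs, among smaller unit checks: a 100-replicate recovery
experiment (200-patient cohorts, ~28% treated, confounding on, planted
DAS/PGA effects; the mean pooled coefficient must sit inside the
Monte-Carlo band of the planted value, interval coverage within
[0.88, 0.99]); a paired comparison showing the weighted estimator removes
more than half of the unadjusted estimator's confounding bias (in
calibration runs it removes ~95% of a ~0.38 DAS-unit bias); a
100-replicate null run checking the Wald type-I error per split-time
category; and exhaustive small-sample agreement of the exact tests with
brute-force enumeration (all 2x2 tables with total up to 40 for Fisher;
all within-block permutations for Friedman at 4 blocks x 3 conditions;
all sign assignments for the signed-rank test up to 8 pairs).
`scripts/acceptance.R` re-runs the recovery experiment from scratch and
reports the recovered effect magnitudes.

## Known limitations

* Only treatment weights are modelled — no censoring weights; patients
  lost to follow-up simply contribute fewer visits.
* The weight-estimation step is ignored in the variance (standard
  practice; slightly conservative in theory).
* Glucocorticoid dose is excluded from imputation and from all
  analytical models: its missingness is heavy (41-79% at the nominal
  time points) and plausibly informative, so dose analyses are treated
  as descriptive only.
* Covariate sets for the probability-of-treatment model are a
  defensible reconstruction (the registry analysis did not publish its
  exact lists), chosen as the variables shown imbalanced between
  treatment groups.
* With nobody treated in a cohort, the split-time contrasts are
  reported as inestimable rather than invented; weights are trivially 1.
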