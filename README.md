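# cycmsm

Marginal structural modelling of cyclophosphamide efficacy in juvenile
dermatomyositis.

## The problem

Juvenile dermatomyositis (JDM) is a rare autoimmune disease of childhood.
Cyclophosphamide (CYC) is used as a second-line treatment in severe or
refractory disease, but because randomized trials are infeasible at 2-4
cases per million per year, efficacy evidence must come from registry
cohorts — where treatment is *confounded by indication*: the sickest
children both receive CYC and have the worst outcomes, and that severity
changes over time.

`cycmsm` is an R package for estimating the causal effect of a single,
noncontinuous CYC course on three disease-activity measures — the
modified skin Disease Activity Score (DAS, 0-5), the physician's global
assessment (PGA, 0-10), and the Childhood Myositis Assessment Scale
(CMAS, 0-52, lower = worse) — using a marginal structural model (MSM)
with inverse probability-of-treatment weighting (IPTW):

1. a three-part **probability-of-treatment model** (PoTM): logistic
   sub-models for baseline receipt, initiation, and discontinuation of
   CYC on the clinic-visit grid;
2. **stabilized IPT weights** `w_ij = prod_{u<=j} p_num(u) / p_den(u)`,
   truncated at 20;
3. **weighted outcome regressions** of each score on time since
   diagnosis and a treatment-recency ("split time") factor — never/not
   yet, CYC within the last 6 months, 6-12 months ago, >12 months ago —
   with independence working correlation and bias-reduced
   cluster-by-patient sandwich variance;
4. **multiple imputation** (chained equations, m = 5) of missing
   PGA/CMAS values, every stage run per imputed set and combined by
   Rubin's rules, `T = W + (1 + 1/m) B`.

The package also ships the unadjusted descriptive battery used alongside
such analyses (chi-square with continuity correction, Fisher's exact
test, Wilcoxon rank-sum/signed-rank tests, Friedman repeated-measures
test with Bonferroni-corrected post hocs, median/IQR change summaries),
covariate-balance diagnostics for the weighted pseudo-population, and a
synthetic cohort generator that emulates severity-driven treatment
initiation, so the whole pipeline is testable by parameter recovery
without any patient-level data.

## Worked example

Simulate a confounded 200-patient cohort with a planted effect of -1.19
DAS units for courses started more than 12 months ago, then run the full
pipeline:

```r
library(cycmsm)

cfg <- sim_config(seed = 42)          # defaults: n = 200, ~28% treated,
sim <- simulate_cohort(cfg)           # confounding on, planted effects
sim$cohort
#> cohort_table: 200 patients (57 CYC-treated), 5964 visits
#>   follow-up: median 85.2 months; visits/patient: median 29.5

res <- run_msm(sim$cohort, m = 5, seed = 1)
forest_table(res)
#>   outcome                 category    coef ci_low ci_high  p_value signif
#> 1     das CYC within last 6 months -0.0273 -0.433  0.3781 8.94e-01
#> 2     das      CYC 6-12 months ago -0.3147 -0.897  0.2679 2.87e-01
#> 3     das       CYC >12 months ago -1.3273 -1.767 -0.8877 1.57e-08      *
#> 4     pga CYC within last 6 months -0.2243 -1.223  0.7744 6.57e-01
#> 5     pga      CYC 6-12 months ago -0.6671 -1.878  0.5434 2.78e-01
#> 6     pga       CYC >12 months ago -1.0095 -1.994 -0.0249 4.46e-02      *
#> 7    cmas CYC within last 6 months  0.6546 -4.038  5.3471 7.83e-01
#> 8    cmas      CYC 6-12 months ago  2.5940 -3.204  8.3916 3.78e-01
#> 9    cmas       CYC >12 months ago  1.5696 -3.043  6.1823 5.03e-01
```

Reading the table: visits of patients whose CYC course started more than
12 months ago show, on average, a DAS 1.33 units lower (95% CI -1.77 to
-0.89) and a PGA 1.01 units lower than visits of never/not-yet-treated
patients — recovering this cohort's planted effects of -1.19 and -0.66
within sampling error — while the within-6-months contrasts are null, as
planted.  The unweighted comparison on the same cohort
(`run_msm(..., also_unweighted = TRUE)`) puts the DAS contrast at only
-0.92: confounding by indication masks roughly a third of the effect,
and the weights recover it.  (Across 100 replicate cohorts the mean
recovered effects are -1.18 and -0.65; single cohorts scatter around
them.)

Descriptive side, aligned to nominal months after the start of treatment:

```r
change_summary(sim$cohort, "das", nominal = c(0, 6, 12, 24))$summary
#>   nominal_month  n median  q1  q3 pct_missing
#> 1             0 57    3.7 3.2 4.3         0.0
#> 2             6 57    3.4 2.9 3.9         0.0
#> 3            12 53    2.7 1.9 3.5         7.0
#> 4            24 43    2.3 1.9 2.7        24.6
```

## Not in scope

Censoring/loss-to-follow-up weights, g-computation or doubly-robust
estimators, dynamic treatment regimes, autoantibody subgroup analyses,
and graphical forest plots (`forest_table()` is tabular).
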