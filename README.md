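# owfs — overlap weighting vs. fine stratification for claims cohorts

`owfs` is an R package for evaluating two modern propensity-score (PS)
balancing methods head to head — **overlap weighting (OW)** and
**fine stratification (FS)** — when estimating the average treatment
effect (ATE) in claims-style observational cohorts where the exposure is
infrequent and the outcome has low frequency. It is aimed at
pharmacoepidemiologists and biostatisticians who want a reproducible
simulation bench for these methods rather than one-off analysis scripts.

## The methods

With propensity score `e(x) = Pr(Z = 1 | X = x)` estimated by
maximum-likelihood logistic regression:

- **Overlap weighting** gives exposed subjects weight `1 − e(x)` and
  unexposed subjects weight `e(x)`. No subjects are pruned, and on any
  converged MLE logistic fit the weighted means of every covariate in
  the model balance *exactly* (the small-sample exact-balance property);
  the estimand is the ATE in the overlap population (ATO).
- **Fine stratification** cuts the *exposed* group's PS distribution
  into K equal-frequency strata (default K = 20), assigns controls to
  those strata, drops strata lacking either group, and weights stratum
  members by either of two ATE schemes: `equ` (exposed `N_i/N_1i`,
  unexposed `N_i/N_0i`; equal group weight totals) or `unequ`
  (`(N_i/N)/(N_1i/N_1)` and `(N_i/N)/(N_0i/N_0)`; group totals equal
  group sizes).

Seven methods are compared: `crude`, `OW_F`, `OW_X`, `FS_F_equ`,
`FS_X_equ`, `FS_F_unequ`, `FS_X_unequ`, where `F` is the full dataset
and `X` the dataset after removing subjects unmatched on the
cross-classification of all binary covariates.

The pipeline is plasmode-style: covariate rows of a base cohort are
resampled with replacement (preserving their joint distribution), then
exposure and/or outcome are regenerated from logistic models whose
intercepts are calibrated by bisection so marginal prevalence/risk hit
scenario targets (e.g. outcome risks 1–30%, exposure prevalence
2.5–30%, or the "observed" levels 27.75% / 10.55%), with a homogeneous
or moderator-dependent treatment effect (true coefficient 1) injected
into the outcome model. Effects are estimated as log relative risks by
a weighted GLM of outcome on exposure alone with a log link, with
cluster-robust sandwich standard errors clustered on the originating
base subject. Balance is scored by per-covariate standardized mean
differences (SMD, reported ×100) and the Mahalanobis balance distance
`MB = d'S⁻¹d` between weighted group mean vectors; estimation quality
by relative bias, SD of relative bias, rMSE, coverage, coverageT (CI
covers the truth *and* excludes zero), and significance, each with
Monte Carlo error.

Because the motivating Medicaid claims data are restricted, the package
ships a synthetic base-cohort generator (Gaussian copula over 5
continuous and 12 binary covariates, with a mutually exclusive race
block and a complementary eligibility pair) that emulates that cohort's
statistical shape: N = 42,628, exposure 10.55%, outcome 27.75%, female
63.59%.

## Worked example

```r
library(owfs)
base <- generate_base_cohort(cohort_config(n_subjects = 10000, seed = 2026))
mean(base$exposure)  # 0.107   (target 10.55%)
mean(base$outcome)   # 0.275   (target 27.75%)

fit <- fit_propensity(base)
ow  <- overlap_weights(fit, base, "OW_F")
st  <- fine_stratify(fit, base, 20)
fse <- fs_weights(st, base, "equ", "FS_F_equ")
balance_table(list(crude = balance_report(base, crude_weights(base)),
                   OW_F = balance_report(base, ow),
                   FS_F_equ = balance_report(base, fse)))
```

```
     covariate     crude  OW_F   FS_F_equ
1          age     2.273     0 -3.156e+00
2     distance   -21.820     0 -3.751e+00
3  elig_months   -46.545     0  2.735e-01
...
18          MB     0.362     0  6.699e-03
19      N_used 10000.000 10000  9.934e+03
```

The crude columns show substantial confounding (SMD ×100 up to ~47; MB
0.36); OW drives every SMD and the MB to zero at machine precision
while keeping all 10,000 subjects; FS gets within a few SMD points with
a small loss of subjects (66 here, from non-overlap and empty strata).

A small simulation scenario (10% outcome risk, observed exposure,
homogeneous true effect 1, 50 replicates of n = 4,000):

```r
sc <- scenario_config(outcome_risk = 0.10, exposure_prevalence = "observed",
                      n_per_replicate = 4000, n_replicates = 50,
                      master_seed = 11)
summarize_scenario(run_scenario(sc, base))
```

```
     method  mean_mb mean_rbias sd_rbias  rmse coverage coverageT significance mean_n_used
      crude 3.97e-01      -42.2     14.2 0.445        6         6           98        4000
       OW_F 8.53e-27      -18.1     14.6 0.232       70        70          100        4000
       OW_X 1.67e-28      -17.6     14.7 0.229       70        70          100        3601
   FS_F_equ 1.63e-02      -22.6     16.6 0.280       60        60          100        3922
   FS_X_equ 1.43e-02      -20.0     15.8 0.254       66        66          100        3522
 FS_F_unequ 1.63e-02      -22.6     16.6 0.280       60        60          100        3922
 FS_X_unequ 1.43e-02      -20.0     15.8 0.254       66        66          100        3522
```

Read: OW achieves the smallest MB and relative bias and the best
coverage; FS sits between OW and the crude analysis; all weighted
methods carry negative relative bias because the outcome is generated
on the logit scale but the estimand is a marginal log relative risk
(confounding grows with outcome risk). `coverageT ≤ coverage` by
construction.

## Command line

```sh
Rscript -e 'owfs::owfs_cli()' generate --out base.csv --seed 1
Rscript -e 'owfs::owfs_cli()' run --scenario scen.json --cohort base.csv --out-dir out/ --replicates 50
Rscript -e 'owfs::owfs_cli()' report --summaries out/<id>_summaries.csv --out-dir report/
```

Scenario/cohort configs are JSON; every run writes a manifest with
seeds, paths, and timings so any replicate can be replayed.

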