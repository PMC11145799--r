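---
title: "Methods: overlap weighting vs. fine stratification in simulated claims cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap weighting vs. fine stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`owfs` benchmarks propensity-score (PS) balancing methods for the
average treatment effect (ATE) in claims-style cohorts. The causal
setup is standard: binary exposure $Z$, binary outcome $Y$, covariate
vector $X$ of 5 continuous and 12 binary components, and the usual
identification assumptions (exchangeability given $X$, positivity,
consistency/SUTVA). The PS $e(x)=\Pr(Z=1\mid X=x)$ is estimated by
maximum-likelihood logistic regression with main effects only; PS-model
misspecification is deliberately out of scope, so the estimated model
matches the generating family.

Three weighting families are compared on full (`F`) and pruned (`X`)
data:

* **Crude** — all weights 1, raw data.
* **Overlap weights (OW)** — exposed $1-e(x)$, unexposed $e(x)$. On a
  converged MLE logistic fit the weighted covariate means balance
  exactly; this is an algebraic consequence of the logistic score
  equations, and the package exploits it as a stringent correctness
  check (the test suite requires $|{\rm SMD}| < 10^{-6}$ and
  ${\rm MB} < 10^{-10}$ after OW). The estimand is the ATE on the
  overlap population (ATO).
* **Fine stratification (FS)** — boundaries are the $0, 1/K, \dots, 1$
  quantiles of the *exposed* group's PS (default $K=20$); controls
  outside the exposed PS range are excluded as non-overlap; strata
  without both groups are dropped, excluding their members. Two
  published ATE weight schemes are provided: `equ`
  ($N_i/N_{1i}$, $N_i/N_{0i}$; group totals both equal the retained
  sample size) and `unequ` ($(N_i/N)/(N_{1i}/N_1)$,
  $(N_i/N)/(N_{0i}/N_0)$; group totals equal group sizes).

The `X` dataset removes subjects whose cell in the cross-classification
of all 12 binary covariates contains only one exposure group — a crude
positivity screen. The PS is refit on the pruned data before weighting
(the alternative, reusing full-data scores, is not documented anywhere
we could anchor it; refitting keeps every analyzed dataset
self-contained).

## Effect estimation

On each analyzed dataset the effect is the log relative risk from a
weighted GLM of outcome on exposure alone (no covariate adjustment —
after balancing, a weighted difference in means is the estimator).
The primary family is binomial with log link (fit as quasibinomial,
which has identical point estimates and tolerates non-integer
weights); when the log-binomial fit fails to converge the package
falls back to a Poisson-family log-link fit, recording the fallback.
With a single binary regressor the weighted log-binomial MLE is the
closed-form weighted log risk ratio, so convergence failures are rare
outside separation.

Standard errors are cluster-robust (HC0 sandwich, no small-sample
correction): weights are probability weights, not frequency weights, so
the model-based (delta-method) variance is wrong, and plasmode
replicates that duplicate a base subject are dependent — the cluster is
therefore the originating base subject (`source_id`). On a base cohort
every subject is its own cluster and the estimator reduces to the
heteroskedasticity-robust sandwich (tested). Rescaling all weights by a
positive constant changes neither estimate nor robust SE (tested).

**Separation.** A replicate is flagged (not dropped) when the fit
fails, $|\hat\theta|>10$, robust SE $>50$, or any exposure-by-outcome
margin cell among included subjects is empty. Primary summaries keep
flagged replicates; a sensitivity summary excludes them. Firth or
Bayesian remedies are out of scope.

## Synthetic base cohort: the stated world

Real Medicaid claims are restricted, so the base cohort is synthetic
and emulates the empirical cohort's shape: default
$N = 42{,}628$, exposure prevalence 10.55%, outcome risk 27.75%,
female proportion 63.59%. Dependence comes from a Gaussian copula over
11 latent dimensions: one per continuous covariate, one per free
binary (female, TANF, urban, insulin), one for the six-level race
block (cut at cumulative category quantiles, so exactly one indicator
per subject), and one for the complementary blind-disabled/adult
eligibility pair. Exhaustive blocks cannot carry per-indicator
correlations, which is why the latent space is 11- rather than
17-dimensional.

Marginals (all configurable; the text the package follows names the
covariates but not their distributions, so these are one-time
"right-shaped" choices, not tuned values):

| covariate | default marginal | rationale |
|---|---|---|
| age | truncated normal, mean 44, SD 12, on [18, 64] years | working-age adult cohort |
| distance | lognormal, meanlog 1.8, sdlog 0.9 (miles) | right-skewed travel distance |
| eligibility months | discretized truncated normal, mean 10, SD 3.5, on [0, 12] | most beneficiaries near full-year |
| managed-care months | discretized truncated normal, mean 8, SD 4.5, on [0, 12] | more dispersed than eligibility |
| Elixhauser count | discretized lognormal, meanlog 0.6, sdlog 0.75 | skewed comorbidity count |

Binary prevalences other than female (0.6359) are plausible claims
values (race block 0.36/0.25/0.02/0.05/0.24/0.08; blind-disabled 0.35;
TANF 0.15; urban 0.75; insulin 0.30). Latent correlations are moderate
and clinically signed (e.g. age–comorbidity 0.35, distance–urban
−0.40, eligibility-months–managed-care-months 0.50).

Exposure and outcome coefficient defaults are log-odds in
$[-0.5, 0.5]$ applied to standardized continuous covariates and raw
indicators, with 13 of 17 covariates nonzero in both models — more
than half the covariates are confounders, matching the described
empirical structure. Intercepts are calibrated (below) so marginal
rates hit their targets.

**What the generator does not emulate:** the real cohort's actual joint
distribution, covariate interactions beyond pairwise latent
correlation, within-subject longitudinal structure, or measurement
error. A green qualitative test therefore establishes that the
*method orderings and trends* reproduce under a structurally similar
world, not that any printed empirical value is recovered.

## Plasmode simulation

Each replicate resamples `n_per_replicate` (default 4,000) covariate
rows with replacement from the base cohort, preserving covariate
associations. Exposure is redrawn from
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(c + \alpha'x))$ unless the
scenario keeps the resampled "observed" labels; the outcome is always
redrawn from
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(c + \gamma'x + T))$ with
treatment term $T=\beta Z$ (homogeneous), $\beta Z M$ (heterogeneous;
$M$ = female indicator, or age standardized to mean 0/SD 1). The
"observed" outcome token calibrates to the base cohort's realized risk
— truth must still be injected, so observed-risk scenarios re-simulate
$Y$ rather than reusing base labels.

**Truth bookkeeping.** $\theta = \beta$ for homogeneous effects;
$\theta = \beta \cdot \bar M_{\rm base}$ for heterogeneous effects,
computed once from the BASE cohort so all replicates share one truth.
For the continuous (age) moderator the standardized mean is 0, making
relative bias undefined; the package refuses to guess and requires an
explicit `truth_override` for that scenario type.

Note the deliberate link mismatch: outcomes are generated on the
*logit* scale with conditional coefficient 1, while the estimator
targets a marginal *log relative risk*. Unadjusted confounding plus
non-collapsibility make all methods increasingly negatively biased as
outcome risk rises — reproducing that pattern is part of the
evaluation, not a defect.

## Numerical choices

* **Intercept calibration**: monotone bisection on $c \in [-50, 50]$
  to $|{\rm mean\ prob} - {\rm target}| < 10^{-8}$, per replicate
  (exposure on the replicate at hand; outcome after exposure
  assignment). Unbracketed targets raise a calibration error naming
  the target.
* **PS fitting**: IRLS with deviance tolerance $10^{-12}$ so the score
  equations — and hence OW's exact balance — hold to near machine
  precision; scores clipped to $[10^{-12}, 1-10^{-12}]$; separation
  flagged on fitted probabilities at 0/1 or $|\hat\beta| > 15$. One
  reference level is dropped per exhaustive block before fitting (the
  score space is unchanged); rank deficiency errors name the collinear
  columns.
* **Stratum ties**: right-closed intervals, first interval closed —
  subjects exactly at an internal boundary fall to the lower stratum;
  duplicated quantile boundaries collapse strata deterministically.
* **Balance denominators**: SMD uses the *unweighted* pooled SD
  $\sqrt{(s_1^2+s_0^2)/2}$ and MB the *unweighted* covariance matrix,
  both over the included sample, so weighting moves only the mean
  differences and crude/weighted values share one scale. A consequence
  worth knowing: because `equ` and `unequ` FS weights differ only by a
  per-group constant, their normalized weighted means — and hence
  their SMD and MB — coincide exactly under this convention. MB is the
  quadratic form (not its root); singular covariance falls back to a
  pseudo-inverse with a warning. The exhaustive race block contributes
  levels-minus-one columns to MB; SMD is still reported for every
  level.
* **Seeds**: a splitmix-style integer mix derives replicate seed
  $s_r$ from (master seed, $r$), keeping all seeds below $2^{31}$;
  identical configs yield byte-identical replicate streams.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| `k_strata` | 20 | published FS studies used 10–100 with similar results; 20 gives ~0.05 average stratum width at the observed prevalence |
| `n_per_replicate` | 4,000 | the benchmark design's replicate size |
| `n_replicates` | 500 | enough that Monte Carlo error is small relative to method differences (MCE is reported) |
| `effect_coefficient` | 1 | the benchmark's true conditional effect |
| separation cutoffs | $|\hat\theta|>10$, SE $>50$ | an order of magnitude beyond any plausible log-RR in these designs |

## Known limitations

* FS `equ`/`unequ` cannot be distinguished by the package's balance
  metrics (see above); their estimation results are identical by
  construction since normalized weighting is shared.
* OW estimates the ATO, not the ATE proper; at low exposure prevalence
  ATO approximates the ATT.
* The scenario grid's rare-event × rare-exposure heterogeneous cell is
  disabled by default (separation-dominated); it can be enabled
  explicitly.
* Only logit-generated binary outcomes and logistic PS models are
  supported; survival outcomes, ML-based PS estimation, and
  misspecification experiments are out of scope.
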