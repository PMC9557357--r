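---
title: "Decomposing catastrophic health expenditure by disease area: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing catastrophic health expenditure by disease area: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Catastrophic health expenditure (CHE) — out-of-pocket (OOP) health spending
that exceeds a fixed fraction of a household's capacity to pay — is a
standard measure of a health system's financial risk protection. Most CHE
statistics are reported in aggregate; health policy, however, increasingly
needs to know *which diseases* drive CHE, because the policy response to a
single expensive hospitalization (catastrophic health funds, inpatient
insurance) differs from the response to chronic-care costs that accumulate
over many small encounters (subsidized medicines, outpatient coverage).

`chedecomp` implements, as a tested and reusable pipeline, a decomposition
of CHE by disease area — non-communicable diseases (NCD), communicable
diseases including maternal and child health (CD), and injuries — from
household-survey microdata of the kind collected by multi-country ageing
and adult-health surveys: complex multistage samples with strata, primary
sampling units (PSUs) and survey weights; per-respondent counts of
inpatient and outpatient visits over the past year; the *reason* for care
observed only for the three most recent visits per care level; and the OOP
cost observed only for the single most recent visit per care level. Because
such microdata are restricted, the package ships a synthetic generator that
reproduces this observation structure with known ground truth, so every
stage can be validated by parameter recovery.

# The estimation chain

## 1. Cause groups

The raw questionnaire offers 18 reasons for seeking care. A codebook
(shipped as an editable CSV, `inst/extdata/reason_codebook.csv`) collapses
them into seven analysis groups: `NCD`, `CD`, `INJURY`, `PAIN`, `SURGERY`,
`OTHER`, `UNIDENTIFIED`. Only the first three are *disease-specific* in the
attribution step; the remainder are retained so that their spending is
never silently assigned to a disease area. The true instrument mapping is
not public, so the codebook is an explicit, swappable input to every
stage rather than a hard-coded table. `CD` includes maternal and child
health reasons, following burden-of-disease grouping conventions.

## 2. Cause imputation

Causes are missing for every visit beyond the three most recent per care
level. `fit_cause_classifier()` trains a probability random forest per
country and care level on the visits with observed causes, and
`predict_cause()` imputes the rest. Features are the respondent's
covariates (age, sex, urban residence, education, wealth quintile), the
care level, the respondent's inpatient and outpatient visit counts, and —
the strongest signal in practice — the counts of each cause group among the
respondent's *other* observed visits (a visit's own label is subtracted
from its feature vector, so no leakage). Chronic care generates repeat
visits, which is exactly what these co-visit features capture.

Defaults (all exposed in `cause_settings()`): 500 trees, square-root
feature subsampling, minimum node size 5, fixed seed. `holdout_accuracy()`
reports cross-validated accuracy with folds grouped by respondent, so a
respondent's visits never straddle train and test. Hard labels are the
modal class, with ties broken deterministically in the canonical group
order; full probability vectors are retained for sensitivity analyses.

## 3. Two-part OOP cost model

OOP costs are observed only for the most recent visit per care level.
`fit_two_part()` fits, per country and care level, (1) a logistic model for
the probability of any spending and (2) a log-link GLM for the positive
amounts — a Gamma GLM by default, or a Gaussian model on log cost with
Duan's smearing retransformation (`family = "lognormal"`). The cause group
(observed or imputed) enters as a covariate with CD as the reference level,
so the exponentiated `causeNCD` coefficient is the estimated NCD-vs-CD
positive-cost ratio. `predict_cost()` returns the *expected* cost,
$\hat p \times \widehat{E}[Y \mid Y > 0]$, never a stochastic draw: the
imputation targets the mean while smoothing visit-level noise (see
*Limitations*). Covariate sets can be chosen by `select_covariates()`,
which minimizes out-of-sample RMSE of expected versus observed cost
(zeros included) under cross-validation grouped by respondent — grouped
because predictions are consumed per respondent.

Costs are converted to 2017 international dollars by a positive
purchasing-power-parity factor (`convert_currency()`); the same factor is
applied to household expenditure and food expenditure, which makes the CHE
flags invariant to the choice of currency unit (a tested equivariance).

## 4. Annual OOP by disease

For the three most recent visits the observed cause is used; for the most
recent visit the observed cost; everything else is imputed/predicted —
observed values always override model output. `annual_oop_by_disease()`
sums per-visit costs by cause group within respondent, and
`household_oop_by_disease()` aggregates over the household's surveyed
respondents. Group totals are conserved: they sum to the grand total to
within 1e-6.

## 5. Capacity to pay and CHE

The subsistence line is the weighted mean of food spending per equivalent
adult among households between the 45th and 55th weighted percentiles of
that quantity (`food_poverty_line()`). Capacity to pay is household
expenditure minus subsistence (`line × size^β`); a household whose actual
food spending falls below its subsistence requirement uses its actual food
spending instead — the convention of the 40%-threshold CHE methodology,
which prevents negative capacities. A household incurs CHE when OOP
spending *strictly exceeds* 40% of capacity to pay.

Each CHE case is attributed to NCD, CD or INJURY if that area exceeds 75%
of the household's *disease-specific* spending (NCD + CD + INJURY only;
PAIN/SURGERY/OTHER/UNIDENTIFIED spending never enters the attribution
denominator); otherwise the case is `UNALLOCABLE`, as are cases with no
disease-specific spending at all. Shares are reported under two
normalizations: percent of all households, and percent of CHE cases (which
sums to 100). `che_by_wealth_quintile()` repeats the decomposition within
wealth quintiles, and `ncd_share_vs_dalys()` joins the NCD share of CHE
with an externally supplied reference table of adult NCD DALY shares (e.g.
from GBD 2019) — the DALY shares are inputs, never computed.

## 6. Uncertainty

`bootstrap_ui()` implements a strata-resampled cluster bootstrap: within
each stratum of $n_h$ PSUs it resamples $n_h - 1$ PSUs with replacement and
rescales that stratum's replicate weights by $n_h/(n_h-1)$ (the Rao–Wu
rescaling bootstrap). The naive scheme that resamples all $n_h$ PSUs
understates between-PSU variance by the factor $(n_h-1)/n_h$ — with the
default eight PSUs per stratum that is a ~6% standard-error deficit, enough
to push nominal 95% intervals visibly below target in our calibration
simulations — so the rescaled scheme is the default (`rescale = FALSE`
restores the naive one). Estimators are recomputed per replicate on the
post-imputation quantities; refitting the imputation models inside each
replicate is deliberately not the default, for tractability. Intervals are
percentile-based; 1000 replicates is the production default. Strata left
with a single PSU are merged with the adjacent stratum, with a message.

## 7. Drivers

`visits_to_che()` computes, for each CHE household, the minimal number $k$
of visits — taken from most to least expensive — whose cumulative OOP
strictly exceeds the threshold amount. The descending-sort prefix is
provably the minimum-cardinality crossing subset, and $k$ is invariant to
the ordering of equal-cost visits; both properties are verified against an
exhaustive subset-enumeration oracle in the tests. This statistic assumes
visit costs are mutually independent (no stop-loss kicking in below the
threshold). `regress_che_shape()` then fits linear probability models for
$k = 1$ (a single spending shock) and $k \ge 5$ (accumulation over many
visits) on an indicator of the disease area causing CHE plus
socio-demographics, restricted to CHE cases, with PSU-clustered standard
errors; `regress_visit_outcome()` runs the analogous OLS models for
per-visit OOP cost and private-facility attendance on the most recent
(non-modelled) visits. Cluster-robust covariances use the one-way cluster
sandwich with the Stata-style $G/(G-1)\cdot(N-1)/(N-K)$ adjustment
(`sandwich::vcovCL` defaults) and $t$ reference with $G-1$ degrees of
freedom. Regressions are unweighted by default (weights optional), with
listwise deletion and explicit dropping of collinear terms.

# Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.40 | CHE threshold as a fraction of capacity to pay; strict inequality |
| `attribution_cutoff` | 0.75 | minimum disease-specific spending share for attribution; strict |
| `band` | (0.45, 0.55) | weighted-percentile band of food spending defining subsistence |
| `equivalence_beta` | 1 | household-size exponent; 1 = per-capita, 0.56 = common equivalence scale |
| `B` | 1000 | bootstrap replicates |
| `cause_settings()` | 500 trees, node 5 | random-forest hyperparameters |
| `cost_family` | `"gamma"` | positive-part family (`"lognormal"` with smearing available) |

"Scaled by household size" is genuinely ambiguous between per-capita and
equivalence-scale readings; the package implements the literal per-capita
default (β = 1) and exposes β = 0.56 as a switch, with both settings tested
against a brute-force weighted-percentile oracle. Likewise, the positive
cost family is not identified by "logit-log-link" alone; Gamma-log is the
standard two-part health-cost choice and is the default, with the
log-normal/smearing alternative implemented rather than merely mentioned.

# The synthetic generator

`sim_config()` / `simulate_sage()` emulate the features the analysis relies
on, with ground truth retained in a sidecar (`$truth`) that estimation code
never touches:

* **Design.** Strata containing PSUs; household weights invert the
  stage-wise selection probabilities, including the oversampling of
  households with members aged 50+ (sampled share 0.55 vs population share
  0.35 by default) and stratum-specific sampling fractions, making the
  design informative. 18–49 households contribute one interviewed adult
  (weight scaled by the number of eligible adults); 50+ households
  contribute all members aged 50+.
* **Utilization.** Negative-binomial visit counts (Poisson as a limit) at
  1.6 outpatient and 0.10 inpatient visits per person-year — typical of
  adult populations in middle-income settings. Each respondent has a latent
  primary cause; visits repeat it with probability `cause_concentration`
  (chronic care), otherwise redraw from a covariate-adjusted mix in which
  age shifts NCD up and CD down. Per-cause visit-rate multipliers allow
  mechanism experiments (e.g. NCD care as many cheap visits).
* **Costs.** Two-part law: zero OOP with probability `1 - p_positive`,
  else log-normal with a log-scale mean linear in cause, care level and
  covariates. The NCD offset is `log(ncd_cost_ratio)` (default log 1.6)
  relative to CD. The default `sdlog = 1.3` gives the heavy right tail
  characteristic of OOP data; together with log-normal household
  expenditure (median 4000/year) and a Beta food share (mean ≈ 0.45) it
  yields CHE rates around 5–8% of households, a realistic magnitude. These
  defaults were calibrated once, against those descriptive magnitudes, when
  the generator was written.
* **Censoring.** `censor_to_sage()` applies the recall pattern — causes
  kept for ranks 1–3 per care level, costs for rank 1 only, counts always —
  as a pure sub-selection: no retained value is altered.

What the generator does **not** emulate: country-specific real-survey
marginals, recall error in visit counts, panel structure or seasonality,
informal payments, within-household correlation of costs, or insurance
stop-loss rules. Passing recovery tests therefore demonstrate that the
estimation chain is consistent with its own assumptions — not that those
assumptions hold in any particular real survey.

# Numerical choices

* Capacity to pay is floored at ε = 0.01 currency units (with a counter);
  households with nonpositive expenditure are excluded from CHE
  denominators and logged.
* Attribution applies the strict `> cutoff` rule with a 1e-9 guard so a
  share lying exactly on the cutoff is never pushed over it by
  floating-point round-off.
* Modal-class ties in imputation break in the fixed group order; identical
  candidate covariate sets tie-break to listed order; `which.min` semantics
  make both reproducible.
* Complete separation in the cost model's logistic part falls back to a
  ridge-penalized fit (glmnet, λ = 1e-3) with a warning; degenerate inputs
  (all costs zero / all positive / single-class causes) return explicit
  constant models instead of errors.
* All stochastic stages are seeded; reruns with the same configuration are
  byte-identical.

# Test problem sizes

The test suite validates oracle equivalences at small n (exhaustive subset
enumeration up to 12 visits; weighted-percentile oracles on dozens of
random fixtures) and recovery/calibration properties at simulation scale:
100 replicates of ~28 000-visit surveys for cost-coefficient recovery, one
20 000-household survey for end-to-end share recovery, 200 repetitions with
200 bootstrap replicates each for interval calibration, and 50 planted plus
30 null replicates for the mechanism contrasts. These sizes were chosen so
that Monte-Carlo error is small relative to the tolerances being asserted
while the full suite runs in a few minutes on one core.

# Known limitations

* **Mean-imputation of costs interacts with thresholding.** Replacing
  unobserved heavy-tailed costs by their conditional means is the method's
  deliberate smoothing choice, but a threshold statistic is not linear in
  costs: households whose *expected* totals exceed the threshold cross it
  deterministically under imputation, while under realized costs crossing
  is a lottery that dilutes systematic cost differences. In our recovery
  simulations this shifts the composition of CHE cases toward the
  higher-mean-cost disease area by roughly 2–3 percentage points (case
  normalization) even when cause classification is essentially perfect,
  while shares normalized by all households are essentially unbiased. Real
  analyses inherit this property; interval estimates do not account for it.
* Attribution granularity is limited by the 18-reason instrument: `PAIN`,
  `SURGERY`, `OTHER` and `UNIDENTIFIED` spending can suppress no case from
  being flagged but cannot be attributed, and the `UNALLOCABLE` share grows
  mechanically with the attribution cutoff.
* The visits-to-CHE construction assumes independent visit costs; insurance
  designs with within-year stop-loss would bias it.
* Bootstrap replicates reuse the fitted imputation and cost models;
  classifier and cost-model uncertainty is not propagated into the
  intervals by default.
* Measuring spending through surveyed respondents only (one adult in 18–49
  households) understates full-household OOP, as household-level CHE
  analyses would define it.
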