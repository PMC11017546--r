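---
title: "Case-crossover distributed-lag models: methods and design notes"
author: "crosslag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-crossover distributed-lag models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslag)
```

This vignette is the package's own account of the statistics it
implements: the design, the model, the choices that were genuinely open,
and what the synthetic verification does and does not establish.

## The design

A case-crossover study treats each person as their own control. For an
acute event on day $t$, the time-stratified scheme takes as referent days
every other day in the same calendar month and year falling on the same
weekday. The calendar forces either 3 or 4 referents, located both before
and after the event day, which protects against bias from long-term trends
in exposure. One event anchors one stratum; a person with several
qualifying events contributes several independent strata
(`build_matched_sets()` works at the person-event level, and no washout
between a person's events is imposed). Referent days are not excluded when
the person happened to have a different visit on them.

Two consequences of month-matching matter downstream:

* **season is constant within every stratum** (month blocks never span the
  Dec–Feb / Mar–May / Jun–Aug / Sep–Nov boundaries), so season main
  effects are not identifiable and must never be entered — only
  PM × season interaction terms are, with a configurable reference season
  (winter by default);
* anything else constant over the month — person traits, address,
  long-term trends — cancels by conditioning, which is the point of the
  design.

## Outcome phenotyping

Records are classified into asthma / LRTI / URTI from ICD-10-CM codes in
the primary or any secondary diagnosis field, against the three
case-definition lists shipped in `inst/extdata/`. Matching is **exact on
the printed code strings** after normalisation (trim, uppercase, dot kept).
The shipped lists mix three-character stems (H65, J04) with fully
specified codes; since no expansion rule is part of the case definitions,
exact matching is the reproducible default and
`respiratory_code_sets(prefix_match = TRUE)` is provided for stem
expansion. A handful of codes are deliberately present in two lists (the
acute-bronchiolitis codes J21.0/J21.8/J21.9 and influenza J09.X2 sit in
both URTI and LRTI); a record carrying one is counted once in each
category, and a record with codes from all three categories anchors three
strata. Admission type is carried through but never filtered on.

## The conditional likelihood and its optimisation

With exactly one case per stratum the exact conditional likelihood per
stratum is the softmax probability of the case day,
$\exp(x_i'\beta)/\sum_j \exp(x_j'\beta)$; Breslow, Efron and "exact"
partial-likelihood variants all coincide here, so no tie machinery exists
in the code. `cclogit_fit()` maximises it by Newton–Raphson with analytic
gradient and Hessian, step-halving on the log-likelihood, starting at
$\beta = 0$, declaring convergence at max $|$gradient$| < 10^{-8}$ or a
parameter step below $10^{-10}$. After the convergence test passes, one
extra polishing Newton step is taken; this costs nothing and makes
algebraically equivalent re-parameterisations (e.g. a different reference
season) agree to near machine precision rather than to the convergence
tolerance. The covariance is the inverse negative Hessian at the optimum;
all inference is Wald with the normal 0.975 quantile, and no
multiple-testing adjustment is applied across windows or modifier levels.

Numerical safeguards: the within-stratum maximum of the linear predictor
is subtracted before exponentiation; a covariate with no within-stratum
variation anywhere raises an identifiability error naming the covariate; a
coefficient escaping $|\beta| > 15$ is treated as monotone
likelihood/separation and the fit is flagged non-converged (a warning, a
`converged = FALSE` flag, and `lincom()` refusing to proceed — never a
silent answer).

## Lag structures and reported odds ratios

All lags run over 0–14 days. The cumulative window $0..k$ includes both
endpoints ($k+1$ terms) — the only reading consistent with the 7-day
windows 0–6, 1–7, …, 8–14 of the weekly-average structure. The cumulative
covariate is the **raw sum**, not the mean; the reported odds ratio is
therefore $\exp((k{+}1)\,b)$ for the sum coefficient $b$, i.e. the
response to a simultaneous 1 µg/m³ increase on every day of the window.
For weekly averages (mean of 7 days) and single-day lags the reported OR
is $\exp(b)$ directly. This convention makes the per-window and joint
parameterisations commensurable: with all 15 single-day lags entered
jointly (`dlm_mode = "joint"`), the window OR is the linear combination
summing the per-lag coefficients over the window, and on
interaction-free data the two modes estimate the same quantity (a tested
invariant).

`dlm_mode = "per_window"` is the default: one conditional-logit fit per
window, each with a single exposure summary (plus modifier terms). The
joint mode with 31–60 parameters is statistically unstable at the stratum
counts typical of the smaller outcome categories, and per-window fits are
what the per-window results table reports; the joint mode is retained as
an option and tested.

## Effect modification

Temperature (daily maximum, °C) varies within strata and enters as a
continuous main effect at a configurable lag 0–6 (default 0 — same day),
plus the PM × T product. Marginal summaries evaluate the PM effect at
three cutoffs, the 15th/50th/85th percentiles of temperature ("colder",
"median", "hotter"), computed by linear interpolation between closest
order statistics (`stats::quantile` type 7) — the common software default;
nothing in the method dictates a percentile definition, so the most
reproducible one is used and an independent hand-rolled order-statistic
oracle checks it in the tests. The percentile population is, by default,
the pooled lagged temperatures of **all case and referent days** of the
category's matched sets; this is a genuinely open choice (case days only
and whole-grid populations are defensible too), so fixed cutoffs can be
passed explicitly to `fit_dlm()`/`pipeline_config()`.

Season modification uses PM × season products for the three non-reference
seasons. Marginal ORs per season add the relevant interaction to the PM
term; re-parameterising with a different reference season leaves them
unchanged (tested to $10^{-10}$). Three-way PM × T × season terms are
excluded by design: with season constant within strata and modest stratum
counts per season they are practically unidentifiable and destabilise the
fits.

## Exposure handling, missingness and aggregation

Exposure lives in an `exposure_store`: complete contiguous daily series
per location, PM2.5 ≥ 0, with per-location coverage windows; extraction
outside coverage is an error naming the location and date. During design
construction the policy is **drop, never impute**: a stratum whose
required lag window (up to 14 days before its earliest day) or
temperature lag reaches outside coverage for any of its rows is dropped
whole, and the count is reported in the run report. Whether to drop or
retain such strata is unknowable from the method description alone;
dropping with a logged count is the conservative, auditable choice.

`aggregate_exposure()` implements the coarse-unit ("Zip-code style")
exposure variant: per unit and day, the **unweighted** mean over member
locations (no population weighting is assumed anywhere), with record
locations re-labelled through the same map.

## The synthetic generator

`simulate_study()` emulates the study conditions the pipeline is meant
for: an 821-day daily series (2017-12-01 to 2020-02-29) at a cold-winter
mountain latitude; log-scale PM2.5 composed of a baseline
(`baseline_log_mean` 1.05 ≈ 2.9 µg/m³ median), a winter seasonal bump
(amplitude 0.45, peaking mid-January — residential wood smoke), a shared
regional AR(1) (φ 0.75, stationary SD 0.28), location offsets (SD 0.25),
local daily noise (SD 0.20), and Poisson-counted summer wildfire episodes
(rate 2 per summer, log-peak 1.5, exponential rise/decay, overlapping
plumes merging via a maximum) — giving daily values spanning roughly
0.5–40 µg/m³ with winter medians above the shoulder seasons; temperature
is an annual sinusoid (mean 7.5 °C, amplitude 11.5 °C, peak late July)
plus shared AR(1) noise (SD 4 °C) and small location offsets. Events are
Bernoulli per child-day under the logistic hazard

$$\mathrm{logit}\,P = \alpha + \textstyle\sum_k \beta_k\,PM_{t-k}
  + \delta T_t + \gamma\,T_t S_t + \theta_{season} S_t + \mu_{season},$$

with $S_t$ the weighted lag sum the modifiers act on; children at one
location share the hazard, so draws pool into one binomial count per
location-day. Records are emitted with ICD codes drawn from the matching
case-definition list (a small "other" share draws respiratory codes
outside all three lists, and a fraction of records carries secondary
codes within or across categories, exercising the classifier). The
category mix defaults to roughly 8% asthma / 6% LRTI / 85% URTI of about
12–13 events per day.

Two generator choices deserve emphasis:

* **Rare-event regime.** The hazard is generative: the case-crossover
  odds-ratio target coincides with the hazard coefficients only while
  event probabilities stay far below 1 on every child-day. A per-day
  log-OR large enough to produce 2–3-fold odds ratios per 1 µg/m³ over a
  realistic PM range would saturate the hazard during smoke episodes and
  bias every estimate toward the null. The default truth therefore uses a
  constant per-day log-OR of 0.004 over lags 0–13 (cumulative 0–13 OR
  ≈ 1.06 — the magnitude typical of large multi-site studies) and a
  temperature interaction of $-1.5\times10^{-4}$ per µg/m³ per °C.
* **Intercept calibration.** By default $\alpha$ is solved so the mean
  event probability equals `baseline_daily_rate` (stable stratum counts
  across truths); `calibrate = FALSE` uses
  $\alpha = \mathrm{logit}(\text{rate})$ directly, under which a stronger
  positive effect raises the realized event count (a tested monotonicity
  property).

One master seed drives everything (exposure uses `seed`, events
`seed + 1`), so a fixed configuration reproduces a study byte for byte.

## What the verification shows — and at what sizes

The test suite verifies, at fixed simulation sizes chosen to keep the full
run in minutes on one CPU:

* **Oracle agreement**: Newton estimates match an independent dense
  grid-search maximiser of the conditional likelihood to $10^{-4}$ on 50
  small random instances, and the closed-form paired toy
  ($\hat\beta = \ln 2$) to $10^{-6}$; coefficients and covariances also
  match an established survival-regression implementation to $10^{-6}$ on
  shared fixtures.
* **Recovery**: over 200 simulated studies of ≈2,000 strata each, the
  pipeline's cumulative and interaction estimates are unbiased (mean bias
  below a quarter of the replicate spread) with 95% CI coverage inside
  [0.92, 0.975].
* **Type-I error**: over 1,000 null studies (≈500 strata each), the Wald
  test rejects at between 3% and 7% at $\alpha = 0.05$.
* **Attenuation**: over 200 paired simulations on a sparse landscape
  (below), the median estimate under unit-aggregated exposure is strictly
  smaller than under address-level exposure (sign test).

What this does **not** show: the generator has no diagnostic coding error,
no exposure-model error at the address level, no time-varying individual
confounders, no demographic structure, and its hazard is exactly the
fitted model's functional form. Passing tests therefore establish that the
pipeline computes its estimand correctly, not that the estimand is
unconfounded in any particular real dataset.

## The aggregation-attenuation study

A subtlety worth recording: unweighted, self-inclusive spatial averaging
of additive, equal-variance location noise is *Berkson-type* error — the
regression of true exposure on the unit mean has slope exactly 1 — and
produces no first-order attenuation; with multiplicative (lognormal)
heterogeneity it can even amplify estimates. Attenuation requires the unit
mean to carry day-to-day variation the resident's own cell does not share
(classical-type proxy error). `simulate_attenuation_pair()` therefore
models the sparse-rural situation in which that happens: each coarse unit
holds one populated cell whose series tracks the shared regional signal
tightly — exposure surfaces are anchored by monitors in population
centres — plus four remote unpopulated cells with much larger cell-level
noise (log-SD 0.55 vs 0.05). The unweighted unit mean then fluctuates with
the remote cells, the proxy error is classical, and the same matched sets
fitted with aggregated exposure give systematically smaller estimates
(≈45% median attenuation at the default settings).

## Known limitations

* Exact-match phenotyping will miss child codes of a printed stem unless
  `prefix_match` is enabled; neither mode consults an external ICD
  hierarchy.
* Strata dropped for missing exposure make the analysed set depend on
  exposure coverage; the run report counts them but no weighting or
  imputation compensates.
* Only unconstrained lag summaries are provided — no spline or penalized
  distributed-lag bases, no humidity or other meteorology, and no
  conditional-Poisson or random-effects alternatives.
* Wald inference can be poor in tiny strata counts (the smallest season
  groups); the fitter flags separation but small-sample bias is not
  corrected.
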