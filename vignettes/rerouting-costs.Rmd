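---
title: "Costs and survival effects of rerouting cancer diagnoses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costs and survival effects of rerouting cancer diagnoses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reroutecost)
```

## The question the package answers

About one cancer in five in England is diagnosed only when the patient
arrives in hospital as an emergency.  Patients diagnosed after an emergency
presentation (EP) have far worse short-term survival than patients whose
cancer is found after a GP referral (non-urgent or urgent two-week-wait,
pooled here as GP/TWW).  Policies that shift diagnoses from the emergency
route to primary care change two things at once:

* **intensity of resource use** — EP patients consume more expensive
  hospital care per month alive, so rerouting *saves* money early on;
* **survival** — rerouted patients live longer, accrue more months of care,
  and therefore *cost* money later.

On top of the hospital costs, each extra GP-route diagnosis requires `1/r`
referrals, where `r` is the conversion rate (share of referrals that turn
out to be cancer); the diagnostic tests of the `1/r − 1` negative referrals
must be charged to the positive case.

This package estimates the full ledger of rerouting one diagnosis —
pre-diagnosis costs, post-diagnosis costs split into the survival and
intensity channels, survival gains — and scales it to a national policy
scenario in which every commissioning region (CCG) is brought down to the
mean EP share of the best-performing 20% of regions.

## The censored-cost three-part estimator

Monthly hospital costs of cancer patients are awkward: follow-up is
right-censored by staggered entry into the registry, and the cost
trajectory is U-shaped, with spikes in the month of diagnosis and in the
last months of life.  Naive averages of observed costs are biased because
censoring removes exactly the expensive terminal months.

`bm_fit()` partitions follow-up into intervals \(j = 1, \dots, J\) (by
default monthly for the first year, quarterly afterwards) and fits, on each
interval's risk set — patients alive at the interval start and not censored
before its end; decedents in the interval are retained —

1. a probit model for death within the interval,
   \(h_j(x) = \Pr(\text{die in } j \mid \text{alive at } j, x)\),
2. a hurdle-gamma GLM for the interval cost of decedents,
   \(\mu^D_j(x)\), and
3. a hurdle-gamma GLM for the interval cost of interval survivors,
   \(\mu^S_j(x)\).

Expected cumulative cost to month \(m\) for covariate row \(x\) with the
route forced is then

\[
\mu(m; x) \;=\; \sum_{j:\, \mathrm{end}(j) \le m} S_{j-1}(x)\,
\bigl[h_j(x)\,\mu^D_j(x) + (1 - h_j(x))\,\mu^S_j(x)\bigr],
\qquad S_{j-1}(x) = \prod_{k<j}\bigl(1 - h_k(x)\bigr),
\]

averaged over a reference population (recycled predictions).  On uncensored
data with saturated (intercept + route) parts this reduces *exactly* to the
per-route empirical mean cumulative cost — a telescoping identity the test
suite asserts to numerical precision.  Under censoring, the interval
structure uses each patient's data for every interval they complete, which
is what repairs the terminal-month bias, at the price of assuming random
censoring given covariates.

### Decomposition into survival and intensity channels

With EP as baseline, the total effect at month \(m\) is
\(\Delta(m) = \mu_{GP}(m) - \mu_{EP}(m)\).  The **intensity** channel
replaces the cost components by the GP/TWW ones while keeping EP survival:
\(I(m) = \tilde\mu(m) - \mu_{EP}(m)\), where \(\tilde\mu\) combines
\(h^{EP}, S^{EP}\) with \(\mu^{D,GP}, \mu^{S,GP}\).  The **survival**
channel is the remainder \(\Delta(m) - I(m)\), so additivity holds exactly
at every month by construction.  A symmetric two-order (Shapley) average is
available via `decompose_effect(order = "shapley")`; the default is the
EP-baseline, intensity-first path.

Two subtleties are worth stating plainly:

* the decomposition is **grid-dependent**: the interval-conditional cost
  components \(\mu^S_j\) absorb how close that route's survivors are to
  death within the interval.  The Monte-Carlo oracle in `true_effects()`
  therefore evaluates the decomposition on the same interval grid as the
  fit.  The total effect is grid-free.
* when end-of-life costs spike, the intensity channel is *not* zero even if
  both routes share the same cost law given the death date, because the
  routes' survivor pools sit at different distances from death.  Only with
  no terminal acceleration does a pure survival contrast produce a null
  intensity channel; the test suite checks exactly that configuration.

### Numerical choices

* Cost GLMs are gamma with log link behind a hurdle for zero-cost
  intervals; hospital cost months are zero-heavy and right-skewed, and
  gamma-log is the costing standard.  Degenerate strata (no positive costs,
  all-positive costs, inestimable designs) fall back to the corresponding
  saturated constants.
* The hazard model is probit by default, logit by option.
* IRLS convergence is tightened (`epsilon = 1e-12`) so saturated parts
  reproduce sample means to ~1e-9 relative precision.
* Intervals with fewer than five decedents pool their decedent cost model
  with the neighbouring later interval(s); with none they contribute
  \(h_j \equiv 0\).
* Fitted hazards are clamped to \([0,1]\) and fitted mean costs to
  \([0, \infty)\) before combination.
* The recycled-prediction population defaults to the pooled (both-route)
  estimation sample, reading the estimand as a population-average contrast.
* Month convention: month 0 is the diagnosis month, bins are half-open,
  pre-diagnosis months are −12..−1, and the month containing death or
  censoring belongs to the patient's history.  Months without recorded
  activity are zero-cost months, not missing data — hospital datasets
  record activity, not inactivity.

Uncertainty comes from patient-level bootstrap resampling
(`bootstrap_curves()`), with percentile 2.5/97.5 bands; resamples that lose
an entire route arm are redrawn and counted.

## Survival: Weibull AFT, RMST and years of life saved

`fit_weibull_aft()` wraps `survival::survreg` with a Weibull accelerated
failure time law: \(S(t\mid x) = \exp[-(t/\lambda(x))^{k}]\) with
\(\lambda(x) = e^{x'\beta}\) and shape \(k = 1/\sigma\).  The route
coefficient is the log time ratio of GP/TWW relative to EP.  Survival
probabilities and restricted mean survival time (RMST) are population
averages with the route forced.  RMST uses the closed form
\((\lambda/k)\,\gamma(1/k, (\tau/\lambda)^k)\) with adaptive quadrature as
an independent numerical cross-check (they agree to 1e-8 on a grid of
shapes, scales and horizons).  *Years of life saved* is defined as the RMST
difference at the horizon (60 months; 36 for lung) divided by 12 — the
published per-patient life-year quantity is a truncated-horizon construct
and this is its natural reading.

## The ledger and the policy scenario

`build_ledger()` assembles, per site:

| entry | meaning |
|---|---|
| `a` | non-conversion cost per converted case, \(c(1-r)/r\) |
| `b` | risk-adjusted pre-diagnosis (−12..−1) cost difference |
| `c1`, `d1` | survival / intensity channels at 12 months |
| `C`, `D` | survival / intensity channels at the horizon |
| totals | `a+b+c1+d1` and `a+b+C+D` |
| ratios | total at horizon divided by the survival-probability gap, and by years of life saved |

Arithmetic is unrounded internally; report-time rounding is half away from
zero to the nearest pound.  Ratios with zero denominators are flagged
undefined (`NA`), never infinite.  No discounting is applied: all costs are
at constant 2010 prices and the source analysis states no discount rate.

`verify_reference_tables()` rebuilds the four published site columns from
their printed components.  Each derivation step is checked at the precision
the table prints: totals from components, ratio rows from the printed total
they chain from.  All derived cells agree within £1 under that stepwise
reading.  A fully unrounded chain from the components alone is reported
alongside; it drifts by a few pounds on ratio rows because the printed
survival-probability gap carries only three decimals (most visibly the lung
cost per survivor, where 355/0.149 sits about £5 from the printed value).
The published prose also quotes a second, mutually inconsistent set of
totals (e.g. £25,716 against £24,546 for colorectal); this package
reproduces the tabulated chain.

The back-solved conversion rates implied by the printed non-conversion
costs (e.g. 0.0435 for colorectal rather than the 3-decimal 0.043) can be
supplied to `referral_economics()` to match the published `a` exactly;
back-solving supports the \(c(1-r)/r\) attribution for three of the four
sites, which is the form used here.

The policy stage sorts CCGs by EP share, benchmarks against the unweighted
mean of the lowest `floor(0.2 N)` (a diagnoses-weighted variant is a flag),
reroutes each CCG's excess share of its annual site volume, and multiplies
by the per-patient ledger.  Referrals needed are `rerouted / r`; the
non-converted count is referrals minus conversions, and both are reported
because the published aggregate table tabulates total referrals under the
non-conversion label.  The policy window is one year with no dynamic
feedback (no conversion-rate dilution as referral volumes grow).

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces registry-like cohorts with the four features
the estimators rely on:

1. **confounded route assignment** — a logistic model makes older, more
   deprived, more comorbid patients likelier to present as emergencies;
2. **route-dependent Weibull AFT survival** with a multiplicative time
   ratio;
3. **staggered-entry administrative censoring**, independent of survival
   given covariates (entry uniform on a window, censoring at the
   administrative cutoff minus entry, capped at the horizon);
4. **U-shaped costs** — zero-inflated gamma monthly costs (default 35%
   zero months) around a mean with a diagnosis spike (months 0–2), a
   terminal spike anchored to the last three months before the *latent*
   death month (so the cost law does not depend on censoring), a
   route-specific pre-diagnosis level, and an EP intensity multiplier.

Shipped per-site presets (`site_preset()`) are calibrated so arm-level
12-month survival approximates the published cohorts (e.g. colorectal EP
≈ 0.50 vs GP/TWW ≈ 0.79; lung 0.13 vs 0.40) and so the cumulative effect
curves show the documented shape: a first-year dip from intensity savings
that is progressively offset by survival costs, with the prostate-like
preset remaining net cost-saving at the horizon.  The presets target these
ranks, not the published pounds: without the registry's coding mix,
comorbidity weights and cost schedules, exact levels (e.g. weighted
Charlson means) are not reproducible, and no attempt is made.  Passing
tests on synthetic cohorts therefore demonstrate internal validity of the
estimators under the assumed data-generating law — correct recovery of
known effects under confounding and 30% censoring — not agreement with any
particular registry's numbers.  Real data add features the generator omits:
cost dependence on covariates, non-Weibull hazards, informative censoring,
hospital-level heterogeneity and staging.

The parameter-recovery test bed fixes n = 10,000 patients, EP share 0.30
with confounding, \(k = 1\), \(\lambda_{EP} = 18\) months, time ratio 2.6,
intensity ratio 1.6, gamma shape 2 with 20% zero months, and entry/cutoff
windows giving ~30% administrative censoring — a configuration chosen so
the recovery tolerances (10% on the total effect, 3 SE on the time ratio,
5% on years of life saved) sit at roughly 2.5 Monte-Carlo standard errors.
The Monte-Carlo oracle (`true_effects()`) draws a covariate
super-population, shares exponential draws across the two forced routes,
and evaluates monthly cost expectations analytically given the drawn death
times, so its own noise is small at 2×10⁵ draws.  Problem sizes throughout
the test suite (500–20,000 patients, 30–200 bootstrap replicates) are
chosen to keep the full suite in the order of minutes while leaving the
statistical assertions at ≥3σ separation.

## Known limitations

* The estimator assumes random censoring given covariates; informative
  censoring is not modelled.
* Covariates are time-fixed; no competing risks, cure fractions or
  time-varying effects.
* The decomposition is reference-dependent (EP baseline) and
  grid-dependent, as discussed; report the grid with the curves.
* The ledger covers hospital inpatient/outpatient costs plus diagnostic
  non-conversion costs only — no primary or social care, no QALY
  weighting, no lead-time or overdiagnosis adjustment.
* The policy arithmetic is a one-year, no-feedback scale-up; conversion
  rates are treated as fixed as referral volumes grow.
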