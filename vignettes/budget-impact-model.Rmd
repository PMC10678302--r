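---
title: "The gtbudget simulation model: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gtbudget simulation model: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtbudget)
```

`gtbudget` estimates the aggregate financial impact of a pipeline of
late-stage gene-therapy programs: how many diseases will obtain an
approved therapy, when, how many patients will be treated month by month,
what the therapies will cost, and who pays. This vignette is the package's
account of the model itself — the assumptions, the parameters that matter,
the numerical choices, and what the tests do and do not establish.

## Model structure

The unit of uncertainty is the *development program*: the set of trials by
one sponsor against one disease. Each Monte Carlo iteration walks four
stages — success, timing, patients, cost — and failed diseases contribute
zeros. The simulation calendar runs in months, with month 0 = January 2020
and a default horizon of 180 months (through December 2034).

### Program success and correlation

Program `i` succeeds with the phase-3-to-approval probability of its
therapeutic area (see `default_pos_table()`). Successes are coupled by a
Gaussian copula: latent draws `z_i = sqrt(rho) z_0 + sqrt(1-rho) e_i` with
exchangeable correlation `rho` (default 0.9), success iff
`z_i < qnorm(PoS_i)`. Two properties matter and are property-tested:

* the marginal success probability of every program equals its PoS for
  any `rho` — the copula moves joint behaviour only;
* because a disease is approved when *at least one* of its programs
  succeeds, positive dependence lowers the approval probability of
  multi-program diseases, so mean approvals and spending are nonincreasing
  in `rho`.

The choice of a single exchangeable correlation across *all* programs
(rather than within-disease only) matches how the correlation is swept in
the sensitivity analysis and is configurable through
`simulation_config(correlation = )`. The Gaussian family is a modelling
choice, not an estimate; nothing in the data constrains the copula family,
and the correlation sweep is the honest way to show how much it matters.

Two overriding rules precede the copula: diseases that already have an
approved therapy are approved as of 2020-12-31 regardless of draws, and
diseases whose last trial ended before 2017-01-01 with no observed launch
are treated as failed (a trial that old without a filing is evidence of
abandonment). Both dates are configuration.

### Timing

The approval date of a newly approved disease is the end of its *last*
trial plus a BLA-preparation lag plus an FDA-review lag. Each lag is
triangular on [0, 365] days with mode 182.5 — symmetric, so the median is
also 182.5 days, reflecting a typical six-month document-preparation
period and the 60-day-acceptance-plus-ten-month review clock that bounds a
standard BLA decision at one year. Trials with missing declared end dates
get `start + gamma` durations, with the gamma fitted by maximum likelihood
(`fitdistrplus`) to the completed trials of the same registry; imputation
draws are made inside each iteration, so imputation uncertainty propagates
into the bands. Approval months are clamped at month 0: the simulation
starts in January 2020 and earlier spending is out of scope.

### Patients

With `t` months since approval, the month-`t` treated count for a disease
is

```
Patients(t) = rho(t, Theta_max, T_max) * f_elig *
              [ New(t) + E(t, 1, lambda) * Existing_0 ]
```

* `rho` is a linear *penetration ramp* from 0 to a plateau `Theta_max`
  reached at `T_max` months — the standard industry adoption curve.
  Category means: rare diseases (0.40, 6 mo) — small, motivated
  populations with few alternatives; cancers (0.10, 12 mo); general
  chronic diseases (0.01, 60 mo) — entrenched standards of care and very
  large denominators. Per-iteration draws are normal with sd = 10% of the
  mean ("variance set to 10% of the mean" read as a coefficient of
  variation, the common informal usage), clipped to (0, 1] and (0, ∞);
  with the default 10% spread the clips are many standard deviations away,
  so the draw means are unbiased, which the tests verify at 10⁵ draws.
  `dispersion = 0` gives deterministic ramps.
* `E(t, δ, λ) = 2^(−t/λ) − 2^(−(t+δ)/λ)` is the fraction of the
  *original* prevalent stock seeking treatment in `[t, t+δ)`: exponential
  depletion with half-life λ. The default λ = 28.91 months is the unique
  value at which 25% of the stock seeks treatment in the first year
  (`half_life_from_first_year(0.25)`). Window fractions telescope exactly,
  so cumulative existing-patient treatment can never exceed
  `Existing_0 · Theta_max · f_elig` — no mutable stock bookkeeping is
  needed, and the depletion is memoryless in calendar time since approval.
* `New(t)` is the monthly flow of newly diagnosed patients: annual
  incidence / 12, constant within the year. Missing incidence or
  prevalence is filled by the steady-state identity `j = k·i/(1−p)`
  (k-year survival `p`); the two conversions are exact inverses and are
  property-tested as such. Nested disease pairs (a sub-type listed
  separately from its parent) are resolved by subtracting child counts
  from the parent before simulation, once — the adjustment is idempotent.

One discretisation consequence is worth stating: the ramp is evaluated at
the *start* of each monthly window, and `rho(0) = 0` exactly, so the
approval month itself never treats anyone and the first window's slice of
the existing stock (about 2.4% at the default half-life) is never treated.
This is inherent to evaluating the ramp-times-window product on a monthly
grid and is negligible at realistic ramp lengths; it is visible only in
degenerate limits (`T_max → 0`).

### Prices, spending, QALYs

Launch price = price-per-QALY × ∆QALY. The rare-disease rate is calibrated
by least squares through the origin against the two rare-disease gene
therapies launched in the U.S. by January 2020 — onasemnogene abeparvovec
(20.56 incremental QALYs, $2.1M) and voretigene neparvovec (4.63, $425k
per eye) — giving $101,640.7 from the rounded inputs; the package's
default rate is the published $101,663 (the 0.02% gap is consistent with
calibration on unrounded QALY inputs, and the tests use a 0.1% tolerance).
The other-disease rate, $40,797, anchored on launched CAR-T therapies, is
a fixed default rather than re-calibrated because the CAR-T ∆QALY inputs
are not public. The reported fit diagnostics are *totals* — sum of squared
errors and sum of absolute percentage errors — because those are the
quantities the published diagnostics correspond to; mean variants are
available via `mean = TRUE`. ∆QALY itself is a registry input: estimating
it per disease requires clinical-trial-level modelling outside this
package's scope, and the synthetic generator draws category-typical values
(rare 5–25, other 0.5–5). Voretigene is priced per eye; the engine treats
one patient unit as one price unit and leaves eyes-per-patient as a
registry-level choice.

QALYs gained are booked fully in the treatment month (the output of
interest is the cumulative QALY series; no amortisation schedule is
modelled). Spending is therefore linear in both the price rate and ∆QALY,
patients are invariant to them, and neither perturbs the peak-spending
month — all three facts are asserted to machine precision in the tornado
tests.

### Aggregation, discounting, payers

Per-month means and pointwise 5th/95th percentile bands are computed over
iterations; note that for strongly skewed monthly distributions the mean
can legitimately leave a 5–95% band, so only band ordering is an
invariant. Discounting multiplies month `m` by `(1+r)^(−m/12)`; the annual
rate is *not* part of the calibrated model — 3%/yr is the conventional
health-economics default and nominal series are always reported alongside.
Payer shares apply age-group spending shares (not patient shares) to
average annual spending: all elderly to Medicare, 2/5 of minors and 1/7 of
adults to Medicaid, remainder private; components sum to the total by
construction.

Reproducibility: one master seed generates per-iteration sub-seeds up
front, so results are independent of how iterations are batched, and
every random draw (lags, ramps) is made for every disease in a fixed order
whether or not it is used — this keeps perturbed reruns on *common random
numbers*, which is what makes the sensitivity deltas clean.

## Sensitivity machinery

`tornado()` scales one input at a time by ±20% (multiplicatively — ramp
draws, lags, PoS, patient counts, prices, ∆QALY) under baseline seeds and
reports percent changes in peak monthly spending, cumulative nominal and
discounted spending, and the shift in the peak month (argmax of the mean
series, ties to the earlier month). `correlation_sweep()` and
`uptake_sweep()` rerun the engine over ρ and first-year-fraction grids;
the uptake response is monotone only below the baseline — push the
fraction high and the stock is consumed while penetration is still
ramping, so the curve flattens and can turn over. `pipeline_scenario()`
fits a least-squares line to program starts per year, extrapolates it
(truncated at zero) as a yearly Poisson arrival rate, creates each arrival
as a new one-program disease drawn from the registry's own empirical
category/epidemiology mix, and reruns the engine; a zero rate reproduces
the baseline exactly under the same seeds.

## The synthetic-data generator

Real pipeline registries of this kind are assembled by hand from
commercial trial databases and are rarely redistributable, so
`generate_registry()` produces registries with the right *structure*: 57 diseases and 109 trials by default, a
category mix dominated by oncology (weights 0.50/0.35/0.15 for
cancer/rare/general), 1–4 programs per disease, ~20% of trials with
missing end dates, at least one nested disease pair and one
prior-approval disease, log-scale epidemiology per category (prevalent
patients: rare 10²–10⁴, cancer 10³–10⁶, general 10⁵–10⁷) tied to k-year
survival at steady state, and category-typical ∆QALY. Trial starts span
2014–mid-2019 with one-to-five-year durations.

What it does *not* emulate: real co-movement between disease severity,
prevalence and ∆QALY; sponsor-level portfolio structure; eligibility
restrictions below the whole-population level (`eligible_fraction`
defaults to 1, encoding "all patients eligible" when no sub-population
data exist); or any real disease's identity. Passing tests therefore
establish that the *machinery* is correct — marginals, orderings,
conservation laws, closed forms — not that any particular dollar figure
forecasts the real market. Aggregates computed on synthetic registries
(e.g. the README example) characterise those registries only.

## Numerical and testing choices

* The depletion formula is implemented with exponents `−t·ln2/λ` and
  `−(t+δ)·ln2/λ`; the telescoping identity and the 25%-per-year anchor
  pin this form down uniquely.
* Degenerate inputs fail loudly: immortal cohorts (`p = 1`) have no
  steady state; all-equal durations make the gamma shape diverge and are
  rejected with a diagnostic; a triangular lag with zero width returns
  its fixed value (used to make timing deterministic in tests).
* Test problem sizes are chosen so the whole suite runs in about a
  minute: 10⁵ draws for marginal checks (3σ bands), 10⁴ engine iterations
  for the analytic approval oracle, a few hundred iterations elsewhere,
  with seeds fixed throughout. Production analyses should raise
  `n_iterations` to 10⁵–10⁶; the engine's standard error shrinks as
  `1/sqrt(n)` (verified on batch means).
* Monte Carlo matrices are held in memory (`n_iterations × horizon` per
  metric); at 10⁴ iterations and 14 metrics this is ~200 MB. Beyond ~10⁵
  iterations a streaming reduction would be the next step.

## Known limitations

No market competition between therapies for one disease; no patient-type
heterogeneity; no fast-track or accelerated-approval pathways for earlier
phase programs; prices are value-anchored only (no delivery costs, no
outcome-based rebates); the payer split is an age-proxy, not an actuarial
model. These mirror the scope of the modelling tradition this package
implements; all are deliberate.
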