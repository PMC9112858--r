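---
title: "Methods: a controlled interrupted time series evaluation of pre-incision antibiotic prophylaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a controlled interrupted time series evaluation of pre-incision antibiotic prophylaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citsepi)
```

## The design

Since around 2011, UK hospitals have progressively switched the timing of
antibiotic prophylaxis at caesarean section from after cord clamping to
before the surgical incision.  Antibiotics given before incision cross the
placenta, so the switch exposes babies to antibiotics at the moment their
gut is first colonised — raising the question of whether the policy changed
the incidence of asthma, eczema and other immune-mediated conditions in
early childhood, and whether it delivered the reduction in maternal
postpartum infection seen in randomised trials.

Exposure cannot be randomised retrospectively and diagnosis rates drift
over calendar time for reasons unrelated to the policy (coding practice,
diagnostic thresholds, surveillance).  The evaluation therefore uses a
*controlled interrupted time series* (CITS): children born vaginally are
never exposed to surgical prophylaxis, so their incidence series absorbs
the secular trend, and the policy effect is identified from how the
caesarean series departs from the vaginal series as the policy uptake
rises.

The core model is Poisson regression on person-time at risk.  Each child
contributes one observation per year of life (ages 0–4), with events
\(d\) and log person-time offset \(\log t\):

\[
\log E[d] \;=\; \log t + \alpha_{\text{year}} + \alpha_{\text{age}} +
(\alpha_{\text{year}\times\text{age}}) + \gamma\,[\text{caesarean}] +
\beta\, x,
\]

where \(x\) is the exposure to pre-incision antibiotics and
\(e^\beta\) is the incidence rate ratio (IRR).  Two exposure regimes are
supported, mirroring how exposure can be ascertained in the two kinds of
routine data:

* **national** — individual timing is unobserved, so every caesarean birth
  in year \(y\) receives the national uptake probability \(p(y)\) that a
  caesarean that year fell under a pre-incision policy.  The probability
  enters linearly on the log-rate scale, so \(e^\beta\) retains the
  interpretation *fully exposed versus unexposed*.
* **hospital** — where the delivering hospital is known, exposure is an
  indicator of birth year strictly after the hospital's policy-change
  year.  Births in the change year itself are excluded (the year is a
  mixture of regimes), as are births at hospitals whose policy year is
  unknown.

The uptake curve \(p(y)\) is estimated from a survey of hospitals: the
caesarean births in year \(y\) at hospitals that had already changed,
divided by caesarean births at all hospitals with known policy.  Weighting
by births (not a raw fraction of hospitals) makes \(p(y)\) the probability
that applies to a birth, which is the quantity the model needs.

## Model variants and their covariates

`cits()` fits four variants:

| variant | data | covariates | effect |
|---|---|---|---|
| `primary_care` | person-year rows | year of birth, age, year×age, delivery type, exposure | IRR |
| `hes` | person-year rows | year of birth, delivery type, exposure | IRR |
| `maternal` | one row per delivery | year of delivery, delivery type, exposure | risk ratio |
| `continuous` | one row per delivery | year of delivery, delivery type, exposure | mean difference |

The primary-care variant includes the year×age interaction because
diagnosis drift can differ by age; the hospital-admission variant follows
the covariate set used for such data (no age terms).  Year and age default
to categorical coding with the earliest level as reference — trends are
then unrestricted — with `coding = "linear"` available when a log-linear
trend is known to hold (as in the simulation experiments below, where the
generator's trends are log-linear by construction, so the linear-coded
model is exactly specified and its coverage is interpretable).

Maternal six-week postpartum outcomes are binary, but the effect of
interest is a ratio of risks, not odds; the package therefore fits a
log-link Poisson model to the binary indicator (risk-ratio estimation)
rather than logistic regression.  Confidence intervals are Wald intervals
on the log scale, \(\exp(\hat\beta \pm 1.959964\,\widehat{se})\); no
overdispersion adjustment is applied by default
(`dispersion = "quasipoisson"` rescales the intervals when wanted).
Convergence uses a relative deviance tolerance of 1e-12 with up to 100
IRLS iterations.  Outcomes with fewer than 200 affected individuals are
not modelled at all (`rare_guard()`): the object reports counts only.

Degenerate designs are flagged rather than reported: a constant exposure
column yields `estimable = FALSE`, and a fit with an absurd coefficient or
exploding standard error (a symptom of complete separation) is marked
non-converged.

## Person-time

Time at risk runs from birth to the earliest of the fifth birthday, loss
to follow-up, the administrative study end (31 December 2018), or the
first diagnosis of the outcome; the event indicator is 1 exactly when the
diagnosis date attains the minimum, with ties resolved in favour of the
event.  Durations are plain date differences in days divided by 365.25.
Ages use half-open intervals \([a, a+1)\): an event on a birthday belongs
to the later year of life, the standard epidemiological convention.  The
expansion into per-year-of-life rows conserves total follow-up to within
1e-9 years (a tested invariant), attaches the event to the final row
only, and never emits a row with age ≥ 5.

Because the hazard is constant within each cell, the Poisson likelihood
is unchanged by collapsing person-year rows over covariate cells;
`collapse_person_years()` performs this Lexis-style aggregation and the
simulation loop uses it, making replicate fits cheap without changing any
estimate (also a tested invariant).

## The synthetic cohort generator

No individual-level data can ship with the package — the UK primary-care
and hospital databases it targets are licensed — so the generator
produces cohorts with the statistical structure the analysis assumes,
and the package's empirical claims are claims about those cohorts.

Defaults describe the emulated study conditions: 515,945 children born
2006–2018, caesarean fraction 0.281, 180 hospitals with log-normal size
weights, policy-change years spread over 2008–2013 with a 40% unknown
mass (so roughly 55–60% of births fall at known-policy hospitals),
baseline first-event rates on the events-per-1000-person-years scale
(asthma 9.9, eczema 71.9), a mild secular trend (2% per year) and a
caesarean/vaginal rate ratio of 1.2.  Where the emulated study reports no
value the defaults are ordinary UK figures chosen once: 40% of caesareans
elective, 5% annual loss to follow-up, 1.5% multiple-birth pregnancies,
mean length of stay 3.2 days (caesarean) versus 1.5 (vaginal).

Events arise from a piecewise-constant hazard per year of life,

\[
\lambda(a, y) = \text{baseline} \times \text{agemult}_a \times
\text{trend}^{\,y - y_0} \times \text{RR}_{CS}^{[\text{CS}]} \times
\text{IRR}^{[\text{exposed}]},
\]

with an exponential waiting time within each year — exactly the model the
per-year-of-life Poisson analysis fits, so recovery experiments measure
the estimator, not a model mismatch.  "Truly exposed" means caesarean
birth in a year strictly after the hospital's change year, thinned by a
*compliance* probability (default 1; hospital audits report 70–100% of
women actually receiving pre-incision antibiotics after a policy change).
An "unknown" survey status masks only the *report*: the hospital still
applies a true policy (its change year drawn from the known-category
distribution), because survey non-response does not stop a hospital's
births being exposed — treating unknown hospitals as truly unexposed
would manufacture spurious misclassification in the national regime.
Change-year births are generated as unexposed; they are excluded from the
hospital-regime analysis anyway, and the vaginal control series is
retained in change years by default (a switch drops the whole
hospital-year instead).  Multiple-birth pregnancies generate sibling
records of which exactly one is retained at random.  Loss to follow-up is
geometric per year and independent of outcomes — the generator has no
informative censoring, no practice-level clustering, no within-year
seasonality and no coding error, so passing tests say nothing about those
features of real data.

Maternal outcomes are Bernoulli with delivery-type-specific risks
(composite infectious morbidity 8.61% caesarean / 1.43% vaginal at
baseline) multiplied by a risk ratio under exposure (0.70 for the
composite); length of stay is gamma with an additive −0.23-day shift in
the mean under exposure, so OLS recovers the shift as a difference in
means.

## Operating-characteristic experiments

`study_scenarios()` pre-specifies three experiments, run by
`sweep_scenarios()` with per-scenario seeds derived from the scenario
*name* (so results do not depend on the order scenarios are listed) and
per-replicate seeds derived from the scenario seed by a counter:

* **null-recovery** — 100,000 children per replicate at the asthma event
  rate, true IRR 1, probabilistic exposure, 200 replicates.  Measures
  log-IRR bias (should be < 0.02 in magnitude), 95% CI coverage (92–98%)
  and type-I error (≈ 5%).
* **power-irr-1.18** — detectability of IRR 1.18 under indicator
  exposure at the full primary-care cohort's asthma event scale.  Power
  in a rate model is governed by event counts, so the experiment keeps
  the full cohort's expected events (≈ 16,500) while simulating 100,000
  children by scaling the baseline rate by 515,945/100,000; 25
  replicates suffice because the rejection rate at this information
  level is essentially 1.
* **attenuation-partial-uptake** — true IRR 1.5 with compliance 0.85 and
  probabilistic exposure, 30,000 children × 60 replicates.  When the
  survey-based uptake probability equals the true exposed fraction, the
  error is Berkson-like and attenuation is near zero; under partial
  compliance the assigned probability overstates true exposure and the
  estimate shrinks towards the null.  With compliance 0.85 the expected
  attenuation fraction \(1 - \widehat{\log IRR}/\log IRR\) is about
  0.1, comfortably inside the (0, 0.3) band the design tolerates and
  consistent with the ≤ 15% underestimation the power planning assumed.

These problem sizes are the package's desk-scale choices: large enough
that Monte-Carlo error (tracked as 3 standard errors throughout the test
suite) is small against every acceptance band, small enough that the
whole suite runs on one CPU in minutes.

## Reporting conventions

Rates are expressed per 1000 person-years (per 1000 births for neonatal
outcomes), with log-normal Wald intervals
\(\text{rate} \cdot e^{\pm 1.96/\sqrt{n}}\) — the construction that
reproduces published intervals of this kind exactly — and are undefined
at zero events rather than degenerate.  Display rounding is half away
from zero to 2 decimals (base R's `round()` is half-to-even);
full-precision values are retained in the CSV outputs, and a masking
switch renders counts ≤ 5 as "≤5".  Rare outcomes appear in tables with
their counts and a dash in the model columns; outcomes requested but
absent from the results are listed as missing, never silently dropped.

## Known limitations

* The national regime treats the uptake curve as known once estimated;
  survey sampling error in \(p(y)\) is not propagated into the IRR
  interval.
* Random effects for hospital or practice, sibling-discordance designs,
  and robust/clustered standard errors are out of scope.
* Recurrent events (consultation counts) are not modelled; only first
  events per outcome.
* The change-year exclusion follows a strict reading — birth year equal
  to the change year is excluded, strictly greater is exposed — and the
  ambiguous question of whether vaginal births at a change-year hospital
  should also be dropped is resolved by keeping them (the policy only
  affects caesareans), with the alternative available as a switch.
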