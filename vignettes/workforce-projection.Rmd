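---
title: "Projecting specialist supply and need with annual stock-flow dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting specialist supply and need with annual stock-flow dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(workforcesim)
```

## The model

`workforcesim` projects a specialist medical workforce with a deterministic
system-dynamics model in discrete annual steps. The state (stock) is the
headcount of specialists indexed by specialty, sex and single-year attained
age; flows add to or drain that stock. The balance

$$\mathrm{Stock}(t+1) = \mathrm{Stock}(t) + \mathrm{Inflow}(t) - \mathrm{Outflow}(t)$$

is the annual Euler discretisation of the continuous stock-flow integral
$\mathrm{Stock}(t) = \int_{t_0}^{t}\!\big[\mathrm{Inflow}(s)-\mathrm{Outflow}(s)\big]\,ds + \mathrm{Stock}(t_0)$.
One year is the natural step for workforce planning: admissions, residency
intakes and retirements are all annual administrative events, and sub-annual
resolution would add nothing observable.

The default index space is 43 specialties × 2 sexes × 36 single-year ages
(30–65). Ages start at 30 because essentially nobody completes the 6-year
degree plus 4–5 year residency earlier; they end at the mandatory retirement
age. Counts are continuous reals — fractional people are deliberate. The
model is a deterministic expectation, not a microsimulation; stochastic
rounding would break exact reproducibility without adding information at
national scale.

### Within-year operation order

Flows within a step are applied in a fixed order:

1. **mandatory retirement** — every cell at age ≥ the retirement age exits;
2. **mortality, drop-out, early retirement** — applied multiplicatively to
   the survivors (deaths `c·m`, then drop-outs `c(1−m)d`, then early
   retirements `c(1−m)(1−d)e`), which makes the decomposition of the
   combined survival factor exact;
3. **ageing** — every cohort moves up one year of age;
4. **training completions** of the target year enter at the entry-age
   distribution (default: point mass at age 30);
5. **net immigration** enters over its own age distribution (default:
   uniform over 30–40, sex split 0.5; both configurable). Negative net
   immigration may drain but never overdraw a cell — overdraws are errors
   that name the offending cell.

The order is a genuine modelling choice: alternatives differ in the third
decimal of a year's exits (e.g. whether people who reach retirement age also
face that year's mortality). Retire-first is the convention here because
mandatory retirement is a date-of-birth event at the start of the
administrative year, whereas mortality and drop-out accrue over the year.
Every step writes a flow ledger, and conservation —
`total(t+1) − total(t) = inflows − outflows` — holds to floating-point
exactness, which the test suite asserts on random instances.

### The training pipeline

The inflow with the long delay. A cohort admitted under the numerus clausus
in year $y$ graduates after $D_{med}=6$ years, passes the national residency
examination with probability `exam_pass`, is allocated across specialties in
proportion to the residency positions on offer (capped by those positions),
and completes a $D_{res}\in\{4,5\}$-year residency with probability
`completion`:

$$\mathrm{inflow}_s(t) = \min\!\big(\text{graduates}(t-D_{res,s})\cdot\text{share}_s,\ \text{positions}_s\big)\cdot\text{completion}_s .$$

A policy change to admissions in year $y$ therefore cannot reach the
specialist stock before $y + D_{med} + \min_s D_{res,s} = y + 10$ — the
decade-long lag that makes workforce planning hard, and which the tests
check bitwise (trajectories are identical before the lag horizon). The sex
split of entrants (default 2/3 female, the contemporary intake composition)
is fixed at admission and preserved through the pipeline. Pipeline history
before the first scheduled year defaults to the earliest admission value
held constant (warm-up); disabling warm-up turns queries into errors
instructing the user to supply the historic cohorts. Exam pass and
completion fractions default to 1.

### The need side

Need per specialty is normative: a base-year standard $r_s$ (specialists per
100,000 inhabitants, typically set by expert consensus) evolved by the
annual rate $g_s$ of the specialty's demand group, under a population path
$P(t)$:

$$\mathrm{Need}_s(t) = r_s\,(1+g_s)^{t-t_0}\,\frac{P(t)}{100\,000}.$$

The four demand groups default to +1.3%, +0.6%, 0% and −0.6% per year —
rates used by the US DHHS and common in planning practice. Growth compounds
geometrically; over the 17 years of a 2008–2025 horizon those annual rates
give +24.6%, +10.7%, 0% and −9.7% cumulatively, which is the conversion
behind the published planning tables (their printed +24.50% and −9.70%
reflect rounding).

Population scenarios are geometric interpolations through per-year anchors,
which preserves ordering between scenarios and reproduces the anchors
exactly. The bundled `moderate` path runs through 44,366,332 (2008),
46,333,661 (2015) and 48,018,184 (2025). The `rapid` and `slow` paths are
not published as numbers; their 2025 anchors (49,888,525 and 46,211,959)
are back-solved from the qualitative descriptions that accompany the
baseline — a 2025 density of about 305 per 100,000 under rapid growth, and
a 2025 deficit of about 10% (≈15,200 specialists) under slow growth — and
are package defaults, fully overridable per scenario.

### Gap metrics

The deficit is expressed relative to **supply**:
$(\mathrm{supply}-\mathrm{need})/\mathrm{supply}$, negative in shortage.
This divisor convention is the one consistent with all three published
baseline percentages (−2.0%, −5.3%, −14.3% for 2008/2015/2025); dividing by
need instead would give −12.5% in 2025. Deficits are computed on headcount
by default, with an FTE-based variant behind `run_scenario(fte_deficit =
TRUE)` — the choice matters once FTE ratios drop below 1, and headcount is
the convention that reproduces the published baseline. Aggregate deficit
pools supply and need before dividing; it is *not* the mean of
per-specialty fractions, and a test pins that down. "Under 51" means
attained age ≤ 50. The density metric is `supply × 100,000 / population`.

## Scenarios and schedules

Every policy lever — numerus clausus, residency positions per specialty,
mandatory retirement age, FTE conversion ratios, net immigration per
specialty — is a per-year schedule with carry-forward semantics: a value
set in year $y$ holds until overridden. That matches the baseline
convention that parameters remain at current values, and keeps
configurations short. Validation can require explicit per-year values
instead (`carry_forward = FALSE`), in which case gaps are reported as
`(parameter, year)` errors before anything runs. There is deliberately no
feedback loop from projected shortage to admissions: closing that loop is a
policy decision, and the model keeps policy as exogenous parameters so that
"what if" questions stay well-posed.

`run_scenario()` is fully deterministic — no randomness anywhere, so reruns
are byte-identical and results are hash-stable (the run manifest records a
configuration hash). `compare_scenarios()` aligns aggregate metrics against
the first scenario; `sweep_parameter()` reruns a scenario with one
parameter held constant at each of a list of values, leaving the input
scenario untouched.

## The synthetic-data generator

The real per-specialty inputs behind a national projection (census
headcounts by specialty-sex-age, per-specialty standards and group
assignments) are administrative data that are not redistributable, and the
published results print only aggregates. The generator therefore produces
*synthetic* fixtures calibrated to those aggregates:

- **Pyramids** come from beta-density age profiles in three families:
  `old_heavy` (shape ≈ Beta(6,2), mean age ≥ 50, female share 0.25–0.35 —
  the traditional specialties), `young_feminized` (≈ Beta(2,6), mean age
  ≤ 42, female share 0.60–0.70) and `uniform` in between. Specialty sizes
  are Dirichlet-like draws; the total is rescaled to the calibration target
  exactly.
- **Mortality** is Gompertz-shaped, $m(a) = m_0 e^{\beta (a-30)}$ with
  $m_0 = 5\times10^{-4}$, $\beta = 0.09$ (≈1.2% at 65), female mortality
  0.8× male at every age. Drop-out is constant by sex and higher for women
  (0.6% vs 0.3%/yr); FTE ratios are 0.9 for women and 1.0 for men.
- **`generate_spain_like_scenario()`** assembles a full baseline calibrated
  to the published 2008 aggregates: total supply 141,579, total need
  144,410 (a 2.0% deficit and 319 per 100,000), the moderate population
  path, and a demand-group need-share mix solved in closed form (shares
  0.305/0.445/0.15/0.10 across the four groups) so that aggregate need
  reaches 173,918 in 2025 exactly. Admissions are held at 7,000/yr — the
  approximate size of the national residency intake — with warm-up cohorts
  at the same level; the published baseline additionally assumed a planned
  (unquantified) increase in admissions, which the fixture omits.

What passing tests on these fixtures shows: the arithmetic of the model —
conservation, delays, monotonicities, calibration identities — is right.
What they cannot show: that any particular real specialty's trajectory is
right, because per-specialty sizes, standards and group assignments are
invented. Named per-specialty findings (which specialties run the deepest
deficits) are exactly the outputs that depend on those unpublished inputs
and are out of reach of a synthetic rerun; the package reports them for
whatever inputs the user supplies.

## Numerical choices and degenerate inputs

- Exits decompose multiplicatively (see order above); all conservation
  checks are at 1e-9 absolute on totals of order 1e5.
- With retirement disabled (`retirement_age = Inf`), cohorts ageing past
  the top modelled age leave through an explicit `aged_out` ledger flow, so
  conservation still holds exactly.
- Empty specialties make pyramid fractions undefined; `pyramid_summaries()`
  errors rather than returning silent zeros.
- Deficit fractions require positive supply (the divisor); aggregate rows
  with zero supply are `NA`.
- Specialty ranking sorts by deficit ascending with ties broken by
  specialty id, stably.
- Results CSVs are written at 17 significant digits so a write/read round
  trip is lossless at double precision.

## Problem sizes

The full configuration — 43 specialties × 2 sexes × 36 ages over 18 years —
is a ~3,100-cell state advanced 17 times, which vectorized base R handles
in milliseconds; no compiled code is warranted. The test suite exercises
the full size against a per-cell scalar reference implementation and runs
randomised property checks (100 instances for conservation) in a few
seconds total.

## Worked example

```{r example}
sc <- generate_spain_like_scenario(seed = 1)
res <- run_scenario(sc)
summary(res, years = c(2008, 2015, 2025))
```

The 2008 column reproduces the calibration anchors (deficit −2.0%, density
319.1); the 2025 need hits 173,918 by construction of the demand-group mix.
The supply path beyond 2008 is the synthetic fixture's own projection and
is not calibrated to any published trajectory.

```{r rank}
head(rank_specialties(res, 2025), 5)
```

## Known limitations

- Inter-specialty mobility is not modelled (it is extremely limited in
  practice for certified specialists), nor are sub-national regions,
  sub-annual steps, stochastic demography, or other health professions.
- The need side is purely normative: standards go in, need comes out. The
  model does not estimate standards from vacancy or utilisation data.
- The baseline admission path holds the numerus clausus constant; planned
  future increases must be supplied as schedule entries.
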