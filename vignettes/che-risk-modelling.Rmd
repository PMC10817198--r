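---
title: "Modelling catastrophic health expenditure risk from out-of-pocket surgical costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling catastrophic health expenditure risk from out-of-pocket surgical costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherisk)
```

## The model

`cherisk` estimates the population share at risk of catastrophic health
expenditure (CHE) — an out-of-pocket (OOP) health payment exceeding a
threshold share of income — when a child needs a surgical procedure, and how
much of that risk is removed by reducing OOP payments.

**Income law.** Incomes within a country are gamma distributed. This is a
strong but convenient assumption: the gamma family is right-skewed,
supported on positive incomes, and — crucially — its Gini index is a
function of the shape alone,

$$G(\alpha) = \frac{\Gamma(\alpha + \tfrac12)}{\Gamma(\alpha + 1)\sqrt{\pi}},$$

which lets routinely published Gini indices pin down the shape without any
microdata. `shape_to_gini()` evaluates this identity in log-gamma space (the
naive ratio overflows for large shapes); `gini_to_shape()` inverts it by
bisection on $\alpha \in [10^{-3}, 10^{3}]$. Eighty halvings collapse the
bracket far below the documented $10^{-10}$ Gini tolerance, and the
monotonicity of $G$ makes the inversion deterministic. Ginis outside
$[0.01, 0.99]$ raise errors rather than being clamped: silent clamping would
hide bad data, and no real country is near either end.

The scale parameter is set so the mean equals household expenditure per
capita (HEpc, annual USD per person). HEpc, not GDP per capita, is the
income proxy: household consumption is what an OOP payment actually competes
with, and the calibration stage (below) supports that choice empirically.
Incomes are annual USD throughout; no purchasing-power-parity conversion is
applied, so cross-country comparisons inherit whatever market exchange rates
embed.

**Quintiles.** Five within-country distributions share the national shape,
with means pegged to $\{0.1, 0.3, 0.5, 0.7, 0.9\} \times \mathrm{HEpc}$.
The pegs are taken exactly as stated; whether they were intended as quintile
means or as midpoints of some other construct is not documented upstream, so
the literal reading is implemented. Two consequences worth knowing: the
average of the five quintile means is $0.5 \times \mathrm{HEpc}$, not HEpc
(the construction deliberately shifts mass downward, a conservative choice
for risk estimation), and each quintile distribution reproduces the national
Gini rather than the narrower within-quintile inequality.

**CHE risk.** A household with income $y$ incurs CHE when the OOP payment
$c$ satisfies $c \ge t\,y$ with threshold $t = 0.10$ by default. The
population risk is therefore the income CDF at $c/t$ — a regularized lower
incomplete gamma function, computed by `pgamma()`. Multiplying by the
population gives the expected number of persons at risk; the weak versus
strict inequality is immaterial under a continuous income law.

**Scenarios.** The baseline payment is the country's OOP share of a $200
unit procedure cost ($200 being a deliberate LIC/LMIC-anchored unit cost;
costs in high-income settings are certainly higher, biasing their risks
downward). Reduction scenarios *multiply the baseline payment* by 0.7, 0.5,
0.3, 0.1. The alternative reading — setting every country's OOP *share* to
70% etc. — would raise risk in countries whose baseline share is below 70%,
which contradicts the monotone risk reductions the scenario ladder is meant
to express; the multiplier semantics are the only internally consistent one.

**Aggregation.** Countries are the unit of observation. Group cells (World
Bank income group × quintile × scenario, and likewise WHO region) report the
across-country mean and the standard error of the mean using the $n-1$
sample standard deviation. Equal country weights are the default — SEM error
bars over countries imply country-level observations — with population
weighting available because the choice is not documented upstream; with
equal populations the two coincide exactly. Groups of one country report
SEM 0 with a logged note rather than a missing value, keeping outputs
rectangular. A country's "overall" risk is the unweighted mean of its five
quintile risks, the construction the published group tables obey.

## Calibration

Observed poverty statistics give an independent check on the
(HEpc, Gini) parameterization. Under the gamma law the headcount at line
$L$ is $F(L;\alpha,\beta)$ and the FGT-1 poverty gap is
$F(L;\alpha,\beta) - \frac{\mu}{L}F(L;\alpha+1,\beta)$. `calibrate_mean()`
scans a log-spaced candidate grid — 41 multipliers spanning $[0.25, 4]$
around the observed proxy, so the proxy itself is the central point and
adjacent candidates differ by about 7.2% — and selects the candidate whose
closed-form headcount best matches the observed headcount at $1.90/day,
with the gap at $2.15/day as the accuracy check. Ties break toward the
larger mean (lower risk: the conservative direction). Poverty lines are
converted to annual USD by a factor of 365. When the observed gap is
missing, calibration proceeds on the headcount alone with a logged warning.
`choose_proxy()` runs the same search seeded from HEpc and from GDP per
capita and keeps the proxy with the smaller combined residual
$|\Delta\text{headcount}| + |\Delta\text{gap}|$, ties to HEpc.

Selection uses the closed forms, which are deterministic and exact;
`replicate_poverty_stats()` provides the replicate-sampling counterpart (25
replicate samples by default, matching the upstream procedure's replicate
count) as a stochastic cross-check, not as the selector — selecting on
noisy replicates would only blur an otherwise monotone objective.

**Identifiability.** The calibration objective is informative only where the
poverty line cuts into the income distribution. At upper-middle and
high-income means the $1.90/day headcount is numerically near zero and
essentially flat across the candidate grid, so observation noise of any size
can displace the argmin arbitrarily — a structural fact about the estimator,
not a software defect. The package's parameter-recovery evaluation therefore
distinguishes two regimes: noise-free recovery (exact, all income groups,
because the closed-form objective has a strict minimum at the truth) and
noisy recovery at observation noise sd 0.01, evaluated over LIC and LMIC
synthetic countries where the line is informative; there, at least 95% of
countries are recovered within one grid step. For real high-income
countries the calibration report's residuals flag the flat regime; no
threshold is imposed on the user's behalf.

## The synthetic world

`generate_countries()` emulates the structure of a World Bank-style country
extract with known ground truth: per-income-group uniform ranges for Gini
(0.30–0.55 LIC/LMIC, 0.30–0.50 UMIC, 0.25–0.45 HIC), HEpc (300–900,
800–3000, 2500–9000, 8000–40000 USD/yr), and OOP share (0.30–0.60 LIC/LMIC,
0.20–0.45 UMIC, 0.10–0.25 HIC); a GDPpc/HEpc ratio of 1.3–2.2 (household
consumption is typically half to three-quarters of GDP); log-uniform
populations between 1e6 and 2e8; WHO regions assigned uniformly. Observed
poverty statistics are the generating model's closed-form values plus
truncated Gaussian noise (sd 0.01 by default, truncated at ±3 sd, clipped to
[0, 1]; the two headcount lines are re-ordered if noise inverts them). Ten
countries per group is the default size.

What the generator deliberately does *not* emulate: real countries'
departures from the gamma law (the observed statistics are self-consistent
with the generating model by construction), correlations between indicators
(Gini and HEpc are drawn independently within a group), region–income
structure, and missing-data patterns. Passing tests on synthetic data
therefore demonstrate that the pipeline's estimators recover the parameters
of the model they assume — internal correctness — not that the gamma
assumption fits any particular country.

## Numerical choices and degenerate inputs

- Bisection rather than a quasi-Newton root finder: monotone, derivative-free,
  bitwise-deterministic across platforms.
- `pgamma()` supplies the incomplete-gamma machinery; quadrature of the
  income density is used only in tests, as an independent route to the same
  integral (agreement to 1e-8 relative).
- Zero OOP payment gives exactly zero risk; a zero poverty line gives
  exactly zero headcount; the gap requires a strictly positive line.
- Table presentation rounds to 3 decimals; all differencing (protection,
  equity gaps) is done on unrounded values and only then rounded, so
  protection tables are not differences of rounded risks.
- Problem sizes in the test-suite oracles: one million draws for Monte Carlo
  agreement (3 standard-error bands), 50 synthetic countries for recovery
  experiments, 25 replicates × 10^4 draws for the replicate cross-check —
  sizes at which the checks are sharp while the full suite runs in well
  under a minute.

## Limitations

- Absolute risk levels depend on the exact indicator vintages and unit
  conventions of the input extract; the package validates itself through
  internal identities, closed forms, oracles and synthetic recovery rather
  than by reproducing any specific published absolute level.
- One $200 price point for all countries; direct medical costs only, no
  transport, lodging or lost wages, so true financial risk is understated.
- CHE is the only outcome: poverty-line crossing (impoverishment), health
  outcomes and DALYs are out of scope.
- No household-size equivalization and no within-quintile heterogeneity
  beyond the shared-shape gamma.
- The `pct_urban` input is carried through I/O but unused; no rural/urban
  disaggregation is produced.
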