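---
title: "Modelling the cost-effectiveness of care systems for alcohol use disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of care systems for alcohol use disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alccea)
```

## The model

`alccea` compares two national-level "health care systems" — mixes of
clinical interventions for alcohol use disorders — on a 12-month horizon.
A system is a *scenario*: a set of (disorder class, intervention) entries,
each with a coverage rate (fraction of the eligible population offered the
intervention) and an adherence rate (compliance moderator of treatment
response). The target population is stratified by gender and AUDIT score
band (abstinent, moderate, heavy, hazardous, harmful, dependence); only the
four disorder bands are eligible for treatment.

For a scenario $s$ the model computes:

* **Cost.** $C_s = \sum_{k \in s} N_{d(k)} \, v_k \, c_k$, where $N_d$ is the
  disorder-class population, $v_k$ the coverage and $c_k$ the per-participant
  full economic cost (2009 euros). Costs accrue to everyone covered,
  regardless of adherence.
* **Morbidity averted (YLD).** Treatment effects are standardised mean
  differences $d$. A conversion factor $f = 0.18$ (95% CI 0.16–0.20)
  translates a shift of size $d$ into a downward shift in disability weight,
  so $\mathrm{YLD}_s = \sum_k N_{d(k)} v_k \, a_k \, d_k \, f \,
  (1 - \alpha)$ with adherence $a_k$ (default 0.50) and attenuation
  $\alpha = 0.20$. No disorder-specific disability weights are used.
* **Mortality averted (deaths, YLL).** All interventions are assumed to cut
  pure-alcohol intake $x$ (g/day) by 20%. The gender-specific relative risk
  of all-cause death is $\ln RR = b_1 \ln(x+1) + b_2 x$
  ($b_1 = -0.1030, b_2 = 0.0035$ for men; $-0.0645, 0.0029$ for women).
  Deaths averted in the present year for a stratum are
  $N v a \, \bar m \, [RR(x) - RR(0.8x)] (1-\alpha)$, where $\bar m$ is the
  age-distribution-weighted annual mortality rate; each avoided death
  contributes the remaining life expectancy at its age, giving YLL.
* **DALYs.** $\mathrm{DALY} = \mathrm{YLD} + \mathrm{YLL}$, exactly. Effects
  of different interventions within a disorder class add (the catalog
  interventions are non-overlapping and independent); nothing is discounted
  on the 12-month horizon.

Comparing a base case ($C_0, E_0$) with an alternative ($C_1, E_1$) yields
$\Delta C$, $\Delta E$, the ICER $\Delta C / \Delta E$ (reported as a ratio
only in the north-east quadrant of the cost-effectiveness plane, with
dominance flags elsewhere), net monetary benefit
$\lambda \Delta E - \Delta C$, the acceptability curve
$P(\lambda \Delta E - \Delta C > 0)$ over a grid of willingness-to-pay
ceilings $\lambda$, and benefit–cost ratios
$E \cdot \lambda / C$ per scenario.

## A note on the dose-response formula

The published form of the mortality model reads "$b_2 \ln(x)$" for the
second term, which is undefined at $x = 0$ and cannot return $RR = 1$ for
abstainers, nor reproduce the published band-level RRs. The model therefore
uses $b_2 x$ (linear in grams/day), which anchors $RR(0) = 1$ exactly and
makes every published band RR attainable; the literal log form remains
available via `relative_risk(..., second_term = "log")` for audit purposes.
The curve is J-shaped (protective at moderate intakes), so inverting it
against a target RR below 1 has two roots; `calibrate_band_intakes()` takes
the larger root, keeping calibrated intake monotone in band severity. Which
branch the original implementation used is not stated; the increasing branch
is the only choice consistent with monotone severity.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| conversion factor $f$ | 0.18 (CI 0.16–0.20) | DW per unit $d$ | expert-panel estimate; sampled in PSA |
| attenuation $\alpha$ | 0.20 | fraction | former heavy drinkers retain residual risk; conservative haircut on YLD *and* YLL |
| adherence | 0.50 | fraction | constant across interventions so that cost-effectiveness differences reflect the technologies, not differential compliance; per-entry override supported |
| intake reduction | 0.20 | fraction | assumed pre–post reduction for all interventions; per-catalog-row override supported |
| willingness to pay $\lambda$ | 50,000 | EUR/DALY | conservative national lower bound; CEAC grid 0–50,000 by 1,000 |
| PSA iterations | 500 | — | sufficient in practice; hard cap 10,000 |

Adherence multiplies the effect side only (not costs): partial compliance
moderates treatment response, while delivery costs are incurred for everyone
covered. Attenuation and adherence carry no published uncertainty ranges and
are therefore sensitivity-analysis knobs, not sampled quantities.

## Packaged fixtures and what is synthetic

The package ships the Dutch inputs as versioned CSVs under `inst/extdata/`:
the AUDIT band fractions per gender, the intervention catalog (costs with
uncertainty ranges; effect sizes with 95% CIs), and the three scenario
coverage tables. Percent quantities are stored as fractions; loaders reject
values above 1.

Two fixture components are *not* observed data:

* **Band mean intakes** (`nl_band_intakes.csv`): the grams/day each AUDIT
  band drinks is not published; only band-level relative risks of death are.
  The packaged intakes are obtained by inverting the dose-response curve
  against those RRs (round-trip agreement within 1e-6) and frozen in the
  fixture so runs do not re-calibrate. They are calibration artifacts — the
  "moderate" band, for instance, calibrates to ~89 g/day for men because
  that is where the increasing branch of the J-curve crosses RR = 0.86, not
  because moderate drinkers drink that much. They matter only through the
  RR difference $RR(x) - RR(0.8x)$.
* **Mortality table** (`nl_mortality_synthetic.csv`): generated by
  `generate_synthetic_mortality()` from a Gompertz hazard
  $q(a) = e^{\mathrm{level} + \mathrm{slope}\, a}$ with parameters (men:
  $-9.8, 0.085$; women: $-10.4, 0.088$) chosen once to mimic a Dutch 2009
  period life table (e.g. male $q(45) \approx 0.0025$, remaining life
  expectancy at 45 of ~35 years). Remaining life expectancy uses the
  period-life-table recursion $e(a) = (1-q(a))(1+e(a+1))$ with the table
  closed at age 100 — expected whole years, so a zero hazard gives exactly
  `max_age - age`.

Three mutually inconsistent published population totals exist; the default
is the 987,000 men / 267,000 women pair because it accompanies the AUDIT
band distribution used throughout, with the 993,200/222,800 national
estimate and the 1,255,000 combined total selectable via
`nl_population(which=)`.

## The population totals, and what the default run reproduces

Running the packaged base case against the eHealth-added scenario
deterministically gives total costs of about EUR 238M vs EUR 301M, and about
4,940 vs 9,970 DALYs averted — against published values of 233 vs 319
million and 5,022 vs 10,319 DALYs. Cost totals depend only on the printed
population, coverage and unit-cost tables; the base-case and
substitution-scenario totals land within ~2% of the published figures, but
the eHealth-added total cannot be assembled to EUR 319M from the printed
tables under any of the three population totals (the computed eHealth
increment is ~EUR 63M, not 86M). The package reports what the tables imply.

## Probabilistic mode

`simulate()` on a fitted comparison (or `run_psa()`) draws, per iteration,
one cost per catalog row from a gamma distribution (moment-matched: mean =
point estimate, sd = range/3.92) and one effect per row from an untruncated
normal (sd = CI width/3.92; negative draws propagate to negative burden
averted, so the cost-effectiveness plane can show all quadrants), plus
optionally one conversion-factor draw from
$N(0.18, 0.04/3.92)$. Draws are shared between the two scenarios within an
iteration (common random numbers): this is the only sampling scheme under
which an intervention offered identically in both arms cancels exactly from
every incremental draw, so scenario differences isolate genuine differences
in the technologies — whether the original implementation did so is not
stated. Whether the original gamma was fitted by moments or quantiles is
also unstated; moment matching is used for determinism. The seed is recorded
in every output file, and identical seeds give bit-identical results.

The acceptability curve uses strict inequality in net monetary benefit
(ties are not cost-effective), anchoring the curve at 0% for $\lambda = 0$
when no draw is cost-saving.

## Numerical choices and degenerate inputs

* Calibration roots are found by `uniroot` on the increasing branch with
  tolerance 1e-12 in intake; targets below the curve's minimum raise an
  error naming the band.
* Degenerate uncertainty ranges (low = high) collapse to point masses, and a
  PSA with all distributions degenerate reproduces the deterministic run
  exactly.
* ICER quadrants are exhaustive: NE ratio, dominant, dominated, SW ratio
  with an explicit tag (the published comparisons never reach SW), and an
  undefined flag when both deltas are zero.
* Ages are integers 18–69, weighted by a truncated normal (mean 44.7,
  SD 10.7) discretised to unit bins; strata counts are kept fractional so
  population totals are conserved exactly.

## What passing tests do and do not show

The test suite checks the model's internal contracts (conservation,
scaling, determinism, quadrant logic, distribution moments) and its
agreement with the published Dutch headline numbers on the packaged
fixtures at problem sizes of ~1.25M persons and 500 PSA iterations. The
synthetic mortality table and calibrated intakes emulate the gross shape of
the real inputs, not their values; agreement on DALY totals therefore shows
the computational chain is faithful, not that the fixture equals the
original unpublished life table. Real screening data also arrive as
individual AUDIT scores with sampling noise — `generate_synthetic_audit_sample()`
emulates that — whereas the model consumes band fractions directly.

## Known limitations

Steady-state, 12-month horizon only: no relapse, no longer-term mortality or
quality-of-life effects, no implementation costs of introducing new
technologies, no costs outside the health-care system, and no non-clinical
policy levers (taxation, advertising bans). Mortality feedback on the
population structure within the year is ignored (deaths averted are small
relative to the population). These are properties of the modelled question,
not shortcuts.
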