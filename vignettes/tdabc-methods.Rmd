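---
title: "Costing HIV service delivery with time-driven activity-based costing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing HIV service delivery with time-driven activity-based costing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivtdabc)
```

## The costing model

Time-driven activity-based costing (TDABC) prices care by following the
client through the facility. Two primitives drive everything:

1. **Capacity cost rate (CCR).** Each resource — a nurse, a clinician, a
   consultation room, a piece of laboratory equipment — has an annual cost
   $C$ and a *practical capacity* $M$: the minutes per year it is actually
   available to clients, after leave, training, administration and idle
   time. Its rate is $r = C / M$, in USD per minute. Practical capacity is
   estimated as $\text{days} \times \text{hours} \times 60 \times a$, with
   defaults of 240 working days, 8 hours and availability fraction
   $a = 0.8$ for staff ($a = 1$ for bookable space and equipment); all
   three are parameters because facilities differ and no single convention
   is canonical.
2. **Step cost.** Every timed step of an encounter allocates one resource
   for $t$ minutes and costs $r \times t$.

An encounter's cost breakdown sums step costs by resource category
(human resources; space/equipment), adds **indirects** as a proportion of
the direct human-resources cost (default rate 0.08), and adds
**consumables** — medications, laboratory tests, disposables — as a fixed
per-service-line charge applied only to clients flagged as receiving them.
The fixed-charge convention reflects how consumables follow standardised
treatment guidelines rather than per-client itemisation; it is also the
model's main resolution limit (see *Limitations*).

Indirect allocation proportional to direct labour is the standard TDABC
overhead convention; the allocation basis is a genuine design choice here
because administrative expenses could equally be spread per facility-year.
We allocate per encounter, which keeps every encounter self-contained and
makes the breakdown additive across any subset of encounters.

### Money representation

Money is fixed-point integer cents internally. Each of the four components
is rounded to the cent once (half-even), and the total is the exact cent
sum of the components, so

$$\text{total} = \text{HR} + \text{space/equipment} + \text{indirects} +
\text{consumables}$$

holds exactly for every row, survives annualisation (an integer multiply),
and survives aggregation. This is what makes the published-style summary
table internally consistent rather than consistent only "up to rounding".

### ART stability and annualisation

Clients on antiretroviral therapy are *stable* only if **all** of: at
least 6 months on ART; adherence ≥ 95% over the previous 6 months; no
stage 3/4 opportunistic infection; viral load strictly below 1000
copies/mL; first- or second-line regimen. The inequalities are read
literally: 95% adherence passes, a viral load of exactly 1000 fails.
Stability sets the assumed visit frequency — quarterly (×4) for stable,
monthly (×12) for unstable — and ART costs are annualised by that integer
multiplier, componentwise. All other service lines are single encounters
from facility entry to exit and are never annualised; attempting to is a
usage error, not a silent no-op.

## Summary tables

`summarize_service_lines()` reports, per line: mean, sample SD ($n-1$
denominator; $n = 1$ reports 0 with a warning), and the 25th/75th
percentiles of total cost and of each component. Quantiles use linear
interpolation between order statistics (`type = 7`, the common default),
switchable via `quantile_type` since no single IQR convention is
universal. Category shares are computed from **unrounded** means and only
then rounded to two decimals — the only order under which the printed
shares of a conserved breakdown set sum to 100. A component that is
uniform across all encounters of a line (typically the fixed consumable
charge) gets an `NA` ("not applicable") IQR rather than a degenerate one.

## The equity analysis

### Asset index

Household wealth is proxied by the first principal component of the binary
possession indicators, computed on the correlation matrix (i.e. on
column-standardised items) — the standard construction for asset indices,
since covariance-matrix PCA would let high-prevalence items dominate.
The score is sign-oriented so that a higher index means more possessions,
then standardised to mean 0, variance 1 over the fitted sample. A constant
item is dropped with a warning; fewer than two informative items is an
error because a one-item "index" is just that item.

### The three models

Ordinary least squares of (1) total provider–client minutes, (2) total
cost with consumables and (3) total cost without consumables — the third
outcome is, row by row, the second minus the consumables component — on:
sex, age group (18–30 reference, 31–50, 51–70, 71+), marital status,
education group (0 years reference, 1–2, 3–4, 5+), comorbidity, the asset
index, region (Central reference), facility level (HC III reference),
ownership (public reference) and service-line indicators. P-values are
two-tailed.

Service fixed effects are implemented as service-line indicators plus the
three facility attributes: full facility-by-service dummies would be
collinear with region, level and ownership, which are the quantities of
interest. `facility_fe = TRUE` swaps in facility intercept dummies and
drops the (then-aliased) attributes, for users who want within-facility
identification of the client-level terms. Standard errors are conventional
OLS by default, with cluster-robust (by facility, or any column) as an
option; the default matches the correctly-specified simulation below,
where errors are independent at the encounter level.

The models use per-visit costs for all service lines, including ART:
the regression observations are encounters, and mixing annualised and
per-visit outcomes in one model would conflate visit frequency with
per-visit intensity. Rows with any missing covariate are removed listwise
and counted in the run log. The service-line reference level is
configurable (default `hct`), since reference choice affects only the
intercept parameterisation, not fitted values — a property the test suite
checks by refitting under permuted level order.

## What the synthetic generator emulates

`simulation_config()` defaults describe the study conditions the analysis
assumes: 31 facilities (16 HC III, 10 HC IV, 5 hospitals — allocated
exactly, by largest remainder; regions 8/8/8/7 Central/Eastern/Northern/
Western; 24 public, 7 private) and 1119 adult clients split
233/273/292/285/17/19 across ART-stable, ART-unstable, HCT, PMTCT, PrEP
and VMMC. PrEP and VMMC are deliberately small to exercise small-sample
paths. Sex, age (truncated normal, minimum 18), marriage, education and
comorbidity are calibrated per service line (PMTCT all female, VMMC all
male, ~73% female overall). Possession indicators are thresholded on a
shared latent wealth factor so marginals hit their target prevalences
(clock 11%, grid 35%, bank 17%, cupboard 32%, plus four further items)
while staying positively correlated — which is precisely what makes a
one-factor asset index meaningful.

Step durations are lognormal around pathway-template means: positive and
right-skewed, the character of stopwatch time-and-motion data, though the
distributional family itself is an assumption — no empirical duration
distribution is available to fit. Space/equipment occupancy is modelled as
concurrent pathway rows flagged `client_facing = FALSE`, so rooms are
costed without double-counting provider–client minutes. Consumable
charges default to the per-visit equivalents of the study's published
category means, with receipt probability 1.

**Planted effects** (+35 minutes for Western region, +13 for private,
+12 for HC IV by default) are added to the designated consult-type step of
each pathway. Because they are additive on the minutes outcome and errors
are independent across encounters, OLS is the correctly specified model —
deliberately, so that parameter recovery is a fair test of the estimator
rather than of robustness to misspecification. The ground-truth file keys
planted effects by the fitted model's coefficient labels, so the recovery
harness joins truth to estimates by name.

What the generator does **not** emulate: queueing and contention (step
durations are independent), facility-level random variation in minutes
(cost jitter exists; time jitter beyond the lognormal does not), seasonal
or pandemic-era service disruption, correlated missingness (generated
covariates are complete), and itemised per-client consumable variation.
Passing tests therefore demonstrate that the pipeline is internally
correct and that the estimator recovers known effects under clean
conditions — not that field data meet those conditions.

## Numerical and degenerate-input choices

- Rounding: half-even at the cent, once per component; totals are exact
  cent sums. Durations are recorded to 0.01 minute.
- Zero-duration steps cost zero; an encounter with no steps and no
  consumables costs exactly zero; a zero-time encounter costs exactly its
  consumables.
- Unknown service lines, unknown resources, missing schedule entries,
  duplicate keys and missing clinical fields are hard, classed errors —
  never silent skips or imputations.
- Rank-deficient equity designs raise an error naming the aliased terms
  rather than dropping them silently.
- Determinism: each generator stage seeds its own stream from the
  configured seed (+0, +1, +2), so a fixed seed reproduces every output
  file byte for byte; the pipeline run log contains no timestamps for the
  same reason.

## Problem sizes

The test suite exercises the costing oracle on 1000 random encounters,
summary oracles on samples of 400–500, the asset-index eigendecomposition
oracle at 500×8, and planted-effect recovery on 100 replicates at the full
study size (31 facilities, 1119 clients), checking that each planted
coefficient falls inside its 95% CI in at least 90 of 100 replicates.
These sizes were chosen to match the study scale where the property is
scale-dependent and to keep the suite quick everywhere else.

## Limitations

The fixed consumable charge suppresses within-line cost variation from
medications and tests, so consumable IQRs are "na" whenever receipt is
uniform, and wealth-related disparities *in consumables* are invisible by
construction. Provider time directed at comorbid conditions cannot be
separated from HIV care. Above-site, supply-chain and
programme-management costs are out of scope: the engine costs direct
service delivery only. And the equity models describe disparities, not
mechanisms — whether a disparity reflects vertical equity (more resources
to greater need) or inequity is a judgement the numbers alone cannot make.
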