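---
title: "Costing premature cancer mortality with life-course matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing premature cancer mortality with life-course matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodloss)
```

## The model

`prodloss` implements a human capital costing of premature mortality. The
premise is counterfactual: had a death not occurred, the decedent would have
lived on, worked, and earned income like demographically similar members of
the population. The package quantifies, per decedent and in aggregate, three
outcomes projected from the death year to a horizon year:

* **YLL** — years of life lost, `min(counterfactual death year, horizon) −
  death year`, where the counterfactual lifespan comes from a matched person
  in a life-course population panel;
* **FTE working years** — accumulated weekly hours over the counterfactual
  lifespan, times weeks per year, divided by the hours in a standard
  full-time working year;
* **PVLI** — the present value of lifetime income: the counterfactual annual
  real income stream valued at the base year as
  `PV = Σ_t y_t ((1+g)/(1+r))^t`, with `g` the real wage growth rate, `r`
  the discount rate and `t` the lag in years from the base year.

Decedents are premature cancer deaths: underlying cause in ICD-10 C00–C97
and age under 80 (roughly life expectancy). Each decedent is matched at
random to a panel person sharing their age category, sex and socioeconomic
quintile. Matching uncertainty is propagated by replicating the random
matching (100 replicates by default) with independently derived seeds;
results are replicate means with percentile confidence intervals.

## Matching

Cells are defined by 5-year age bands (0–4 … 75–79), sex, and SES quintile.
The bands are finer than the reporting bands so that age at death is
respected closely, but coarse enough that a one-percent-sample panel
populates nearly every cell. Draws are uniform **with replacement**: a
national decedent cohort (tens of thousands) can exceed a cell's candidate
count in a 20,000-person panel, so each candidate can serve as the
counterfactual for several decedents.

When a cell is empty, a fallback ladder is climbed and every relaxed match
is logged: (1) adjacent SES quintiles are merged; (2) the age band is
additionally widened by one band on each side; (3) SES is dropped entirely.
The steps accumulate, preserving the strongest predictors of labour-force
outcomes — age and sex — for as long as possible. Only if a decedent still
has no candidate (no panel person of that sex near that age) does the run
stop with an error naming the decedent. The candidate index also carries an
open-ended `80+` band so that every person alive in the matching year
belongs to exactly one cell; decedents never key into it, but the
age-widening step of the 75–79 band may draw from it.

Replicate `r` uses seed `base_seed XOR r`. This derivation is part of the
public contract: the same spec and base seed reproduce byte-identical
assignments on any machine.

## Economic parameters

| parameter | default | meaning |
|---|---|---|
| `wage_growth` | 0.01 /year | real income growth applied at valuation |
| `discount_rate` | 0.03 /year | discounting of future income |
| `base_year` | 2003 | present-value base (the mortality year) |
| `horizon` | 2030 | last projected year |
| `standard_annual_hours` | 1976 h | 38 h/week × 52 weeks, the standard full-time year |
| `weeks_per_year` | 52 | annualisation of weekly hours |
| `cpi_factor` | 1 | multiplier to reporting-year dollars (user-supplied) |

Growth is applied to the real stream and discounting to the grown stream —
the conventional net factor `((1+g)/(1+r))^t` with exponent 0 in the base
year (end-of-period convention). With `g = r` the PV is the plain sum of
the real stream. At `r = 3%` a payment 29 years after the base year is
discounted by a little over 57%, which bounds what the 2030 truncation can
leave out; the year-counting convention behind that figure is ambiguous at
27 or 28 years, where the reduction is just under 57%.

Two conventions the data cannot decide were fixed once and documented: the
death year itself contributes a full counterfactual year of potential work
and income (matching happens at the start of the year), and the
counterfactual death year contributes zero (death at the start of that
year, the conservative end). `cpi_factor` defaults to 1 because synthetic
runs have no canonical reporting year; real analyses supply their CPI
ratio.

The panel generator also has a `wage_growth` (default 0.01): the simulated
population's own real-wage trajectory. It composes with the valuation
growth rate; configurations that want growth in exactly one place set the
other to zero (the closed-form validation below does exactly this).

## The synthetic data generator

No individual-level mortality registry or census-based microsimulation can
be shipped, so the package generates both inputs with the statistical
structure the analysis assumes.

**Mortality dataset.** Deaths are drawn multinomially over (age band × sex)
cells — defaulting to the Australian 2003 premature cancer distribution,
25,733 deaths — with integer age uniform within the band (only banded
counts are published), a uniform SES quintile, a cancer site drawn from the
2003 site distribution, and a concrete ICD-10 category drawn uniformly from
the site's code ranges. Site is drawn independently of sex: the two stated
marginals are preserved exactly, at the price of occasional demographically
impossible pairs (a male ovarian-cancer record, say). Matching never uses
site, so no downstream quantity is affected; this is a deliberate
simplification, not an oversight.

**Population panel.** A fixed cohort (default 20,000 persons — one-percent
sample scale) is followed from 2003 to 2030. Starting ages come from a
stylised early-2000s age pyramid; each year survival is resolved against a
Gompertz-shaped age/sex hazard, then participation (0.713 for working-age
men and 0.558 for women in the base year, the 2003 national rates; small
configurable rates at 65–79), part-time status (women more likely, 0.45 vs
0.15), hours (two-point: 19 or 38 per week) and income (full-time-equivalent
base wage by sex and SES quintile with a lognormal person-level factor,
σ = 0.3 — a free parameter, as no income distribution family is published
for the source model). Hours and income are exactly zero in and after the
simulated death year.

What the generator does **not** emulate: migration, household structure,
policy responses, year-to-year persistence of employment beyond the alive
state, correlation between cause of death and risk factors shared with
other mortality. Passing tests therefore demonstrate the correctness of the
costing machinery under the stated marginals, not the realism of any
particular dollar total: absolute synthetic totals depend on generator
parameters that published aggregate tables cannot pin down.

## Numerical and design choices

* Percentile confidence intervals use the linear-interpolation order
  statistic (`stats::quantile` type 7) at 2.5%/97.5%; aggregation always
  sums within a replicate first and only then summarises across replicates,
  and the same rule applies in every stratum.
* Display rounding is half-up (so 81.5% renders as 82%) and is applied only
  when rendering tables; all internal values stay unrounded.
* The shipped site map groups C00–C97 into 26 named sites plus "Other
  malignant neoplasms" using standard WHO category groupings; C97 (multiple
  independent primaries) falls to the catch-all, and "Liver cancer
  (excluding hepatitis B and C related)" is plain C22 because hepatitis
  attribution is not derivable from a cause-of-death code. Users can
  override the map with a CSV (`site_label, code_start, code_end`).
* Degenerate inputs are handled explicitly: zero deaths give empty outputs,
  an empty outcome set renders zero tables with a warning, a single
  replicate collapses the CI onto the mean, and configuration errors
  (weight tables that do not sum to one, nonpositive CPI factors, inverted
  year ranges) name the offending table.

## Validation strategy

The test suite validates the pipeline against independent routes rather
than against published absolute totals (which depended on confidential
registry and census inputs):

* brute-force per-person-year loops must agree with the vectorised
  accumulation to 1e−6 relative error on a 2,000-person panel;
* a constant-income, guaranteed-survival cohort must recover the annuity
  closed form `y Σ ((1+g)/(1+r))^t` exactly;
* 100 matching replicates must be complete, key-consistent, reproducible
  under reseeding, and uniform within cells by chi-square at α = 0.001;
* the mortality generator must reproduce its (age × sex) weight table
  within three multinomial standard errors at the full cohort size;
* published ratio arithmetic (sex shares, site shares, per-death costs,
  reduction-scenario savings) must be recovered from the embedded 2003
  reference tables by the reporting operations.

Problem sizes in the routine suite (panels of 400–3,000 persons, cohorts of
40–25,733 deaths, 2–100 replicates) were chosen so the full suite runs in
seconds while leaving every property at meaningful scale.

## A worked example

```{r example, eval = FALSE}
res <- run_analysis(
  mortality_spec(n_deaths = 2000, seed = 1),
  panel_spec(n_persons = 10000, seed = 2),
  economic_params(),
  n_replicates = 100, base_seed = 3
)
res
aggregate_outcomes(res$outcomes, by = "sex", res$params)
render_tables(res, "tables")

# published-table arithmetic
sites <- aus_cancer_sites_2003()
lung <- sites[sites$site == "Lung cancer", ]
scenario_savings(lung$pvli_m, reduction = 0.02, horizon_years = 10)
```

## Known limitations

Morbidity and carer productivity costs are out of scope (mortality only);
unpaid and household labour are not valued; the friction-cost and
willingness-to-pay alternatives to the human capital approach are not
implemented; and the truncation at the horizon makes all totals
conservative for the youngest decedents. The synthetic panel's absolute
income levels are calibrated only loosely to early-2000s Australian wages,
so synthetic dollar totals are indicative of structure, not of the national
burden.
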