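---
title: "Methods: from indoor radon surveys to lifetime lung-cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from indoor radon surveys to lifetime lung-cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonrisk)
```

`radonrisk` chains four models: (1) population-weighted aggregation of
regional indoor radon surveys, (2) a microenvironment exposure model that
turns radon gas concentrations into annual radon-progeny exposures via
equilibrium factors and time-activity patterns, (3) a windowed
excess-relative-risk (ERR) model evaluated through a double-decrement life
table, and (4) per-location attribution of the excess lifetime risk. A
synthetic-data module supplies survey and mortality inputs with the
statistical structure the analysis assumes, and a Monte-Carlo cohort
simulator cross-checks the analytic life table.

## Survey aggregation

Each survey record is one campaign: a region, its census population, the
building function surveyed, the number of places tested `n_tested`, and the
arithmetic-mean radon concentration (Bq/m³). Aggregation proceeds in two
stages:

1. **Within-region pooling.** When a region reports several surveys of the
   same building class, their means are pooled weighted by `n_tested`. The
   measurement count is the natural weight for combining arithmetic means of
   measurements; population weighting at this stage would double-count the
   region's population.
2. **Between-region weighting.** Regional pooled means are weighted by
   census population. Regions with no data for a class are omitted from that
   class's weighting — absence of data is not a zero concentration.

Building functions map to three aggregation classes: `home`, `school`, and
`public` (civic, provincial, and federal buildings). Senior housings are
classified as residential by default — they are dwellings, and this is the
classification under which the packaged fixture's national measurement
counts are internally consistent (homes 7866, schools 1132, public 1668).
The mapping is an explicit argument, so users can exclude or reclassify any
function.

```{r}
national_summary(radon_survey_fixture())
```

Weighted means are kept at full precision internally and rounded to integer
Bq/m³ only in the `*_display` column.

## Exposure model

Radon gas itself delivers little lung dose; the short-lived progeny do. The
progeny level is expressed as the equilibrium-equivalent concentration
(EEC): the radon concentration times the equilibrium factor
$F_{eq} \in (0, 1]$ describing the degree of radon–progeny disequilibrium.
Defaults follow the assessment's configuration: $F_{eq} = 0.6$ for homes
and outdoor air, $0.4$ for schools and public buildings, with outdoor radon
at the worldwide-average 10 Bq/m³ (EEC 6 Bq/m³). Vehicles are assigned
outdoor air.

Annual exposure at a location is `hours/day × EEC × 365` (h·Bq/m³). A
365-day year is used throughout; it is the convention under which the
packaged exposure table is internally consistent to the last digit. The
"indoors away from home" microenvironment is age-group-specific: public
buildings for infants (15.2 Bq/m³), home-like daycares for young children
(71.4 Bq/m³ — most Canadian child care is in caregivers' homes), schools
for children (24.4 Bq/m³) and adolescents. The packaged adolescent value is
24.2 Bq/m³ as printed in the source survey table rather than the school
value 24.4; the two reproduce different cells, the packaged table keeps the
printed one, and the CSV input makes either available.

Totals and percentage contributions per age group are computed on unrounded
per-location values and rounded only for display (sum-then-round); display
rounding is half-away-from-zero, matching the convention of the printed
tables, with a snap to six decimals so that binary floating-point error
cannot flip an exact decimal half-case.

```{r}
age_group_exposure(time_activity_fixture())$summary
```

Cumulative exposure is measured in working level months,
$1\ \mathrm{WLM} = 6.37 \times 10^5\ \mathrm{h\,Bq/m^3}$ of EEC.
`build_lifetime_history()` expands the six age-group patterns over a
110-year lifespan (years of life 0; 1–4; 5–11; 12–19; 20–59; 60–109),
giving each year its age group's annual per-location WLM. Restricting the
`locations` argument zeroes the others, which is how single-location
histories for attribution are built.

## Risk model

The excess relative risk at attained age $a$ follows the EPA/BEIR-VI
exposure-age-concentration form:

$$e(a) = \beta \left( W_{5-14} + \theta_{15-24} W_{15-24} +
\theta_{25+} W_{25+} \right) \Phi_{age}(a)$$

with $\beta = 0.0634$ per WLM, $\theta_{15-24} = 0.78$,
$\theta_{25+} = 0.51$. The $W$ terms are cumulative WLM received 5–14,
15–24, and ≥25 years before age $a$; exposure in the most recent 5 years is
biologically inert (minimum latency). Windows are computed on whole years
of age: exposure in year of life $y$ counts as received $a - y$ years
before age $a$, and the three windows exactly partition all exposure
received at ages $\le a - 5$. No sub-annual convention is imposed because
the inputs are annual.

$\Phi_{age}$ is a piecewise-constant, non-increasing attained-age modifier.
Its values are a required configuration with the BEIR VI / EPA categories
as the packaged default: 1.00 below age 55, 0.57 for 55–64, 0.29 for
65–74, 0.09 at 75+ (National Research Council, *Health Effects of Exposure
to Radon: BEIR VI*, 1999; US EPA 402-R-03-003, 2003). All exact-value tests
use a flat $\Phi \equiv 1$ or explicit toy values so they do not depend on
this choice.

Lifetime absolute risk uses the BEIR-IV double-decrement life table over
ages 1–110. With lung-cancer hazard $h_i$, all-cause hazard $h_i^*$
(already including baseline lung cancer), and ERR $e_i$ evaluated at
attained age $i$:

$$R_e(a) = \sum_{i=1}^{a} \frac{h_i (1+e_i)}{h_i^* + h_i e_i}
\prod_{k=1}^{i-1} e^{-(h_k^* + h_k e_k)}
\left[ 1 - e^{-(h_i^* + h_i e_i)} \right]$$

Each yearly term is: survive to year $i$ under the total hazard, die during
year $i$, and the death is lung cancer with the hazard-fraction
probability. This construction conserves deaths exactly (lung + other =
total, each year) and makes $R_e$ monotone in $\beta$ and in any single
year's exposure. The total hazard $h_i^* + h_i e_i$ appears in all three
factors; a variant with a minus sign in the final bracket — under which
radon exposure would *reduce* total deaths — is available behind
`printed_sign_variant = TRUE` for comparison only. A year with zero total
hazard in the cause fraction contributes nothing. Baseline risk $R_0$ is
the same table with $e_i \equiv 0$; relative risk $RR(a) = R_e(a)/R_0(a)$
is reported as missing where $R_0(a) = 0$.

All risk computations are per sex; combined-population numbers are the
user's explicit weighted average of the per-sex results.

### Attribution

The share of location $\ell$ in the excess lifetime risk is

$$\mathrm{share}(\ell) = \frac{R_\ell - R_0}{R_{all} - R_0} \times 100$$

at age 110, with $R_\ell$ computed from a history in which only location
$\ell$ is exposed. Because the ERR enters the life table nonlinearly,
shares need not sum to exactly 100; at realistic residential exposures the
deviation is a few tenths of a percentage point, and in the $\beta \to 0$
limit the shares converge to each location's windowed-exposure share and
sum to 100 exactly (both properties are tested).

```{r}
m <- synthetic_mortality_fixture()
attribute_by_location(time_activity_fixture(), mortality_for_sex(m, "male"))
```

## Synthetic data

The generators exist so the full pipeline is testable without external
data.

**Surveys.** Indoor radon is generated lognormally — the standard model for
indoor radon concentrations — with per-class geometric means and GSDs
(defaults: GM 85/45/28 Bq/m³, GSD 2.2/2.0/2.0 for home/school/public,
spanning the wide ranges real campaigns report). A synthetic survey mean is
the arithmetic mean of `n_tested` draws, exactly how a real campaign
summary arises. Generators are deterministic in (config, seed).

**Mortality.** National life tables are not redistributable with the
package, so the packaged mortality table is an explicitly synthetic
stand-in with the qualitative structure the analysis relies on: all-cause
hazard is Gompertz–Makeham, $h^*(x) = c + A e^{Bx}$; lung-cancer hazard is
zero below a sex-specific onset age (10 for males, 20 for females), then
follows a logistic curve rising steeply after mid-life to a plateau
(5.2×10⁻³/y male, 4.0×10⁻³/y female, midpoints 72/74 y), capped at the
all-cause hazard. The default parameters were chosen once to resemble
recent Canadian rates in magnitude; the analytic life table puts the
implied baseline lifetime risks at 0.066 (males) and 0.056 (females) —
the right order of magnitude for a high-income population, which is all the
synthetic table claims. Reproducing published national baseline risks
requires supplying the actual national rates via `read_mortality_csv()`.
Consequently, passing tests demonstrate correctness of the machinery on
inputs with realistic structure, not numerical agreement with any
particular country's lung-cancer burden.

**Cohort simulator.** The independent check on the life-table algebra
simulates a closed cohort year by year: death in year $i$ with probability
$1 - e^{-(h_i^* + h_i e_i)}$, cause assigned lung cancer with the
hazard-fraction probability. Individuals are iid, so the per-year Bernoulli
outcomes are aggregated with binomial draws — distributionally identical to
an individual-level loop and fast enough for cohorts of $10^6$. Agreement
with the analytic formula within 3 binomial standard errors is asserted on
a grid of fixed and randomized hazard/ERR scenarios ($10^6$ individuals
per scenario).

## Numerical choices and degenerate inputs

- Full precision everywhere internally; rounding only in `*_display`
  columns (half-away-from-zero with a 6-decimal snap).
- Daily hours must sum to 24 ± 0.01 per age group; hazards must satisfy
  $0 \le h \le h^*$, $h^* > 0$, over ages 1–110 exactly.
- Empty survey tables, unmapped building functions, mixed-region pooling,
  zero total population, and zero-excess attribution all fail fast with
  named errors rather than returning degenerate numbers.
- Exposure year 0 (infancy) maps to the first life-table year; exposures at
  ages above 105 can never affect $R_e(110)$ because of the 5-year latency
  (tested).

## Known limitations

- No dosimetric lung-dose modelling (ICRP conversions), aerosol physics, or
  seasonal variation; equilibrium factors are configuration, not physics.
- No smoking interaction and no uncertainty propagation; $\beta$ and the
  window weights are treated as known constants.
- Within-survey distributions are summarized by their arithmetic means;
  detection-limit imputation and geostatistics are out of scope.
- The synthetic mortality table supports order-of-magnitude and structural
  conclusions only; per-location attribution shares are robust to this
  (they depend mostly on the exposure ratios), but absolute risks are not.
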