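---
title: "Methods: an integrated scenario model of a rural coastal delta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated scenario model of a rural coastal delta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltasim)
```

deltasim is a desk-scale integrated assessment model of a low-lying,
polder-protected rural delta in the style of coastal Bangladesh. It
couples scenario-driven environmental forcing (sea-level rise, climate
anomalies, cyclones), a reduced-form flood model, a daily soil water and
salt balance, crop-coefficient yield modelling, and a monthly household
microsimulation, and analyses the coupled system with a one-at-a-time
(OAT) sensitivity ensemble. This vignette documents the model equations,
the free parameters and their defaults, the synthetic-data generator, the
numerical choices, and the known limitations.

## Scenario worlds and drivers

Two internally consistent futures are encoded as parameter bundles
(`load_world()`): a *positive* world (median sea-level rise of 38.5 cm at
mid-century relative to 2000, maintained embankments, crop improvement
with the rice salinity tolerance ramping from 6 to 13 dS/m and +20% unit
production, 2.5%/yr economic growth, constant 14 M population) and a
*negative* world (73.5 cm sea-level rise, embankments declining 3 cm/yr,
no crop improvement, 0.6%/yr growth, outmigration to 11 M). The base
period is 2000--2015 and the mid-century window 2040--2055.

Driver series are pure functions of the configuration:

* **Sea level** rises quadratically from 0 in 2000, scaled so the
  2040--2055 mean equals the configured value. A quadratic was chosen
  because an accelerating rise matches the sea-level-rise literature
  without introducing extra shape parameters.
* **Climate anomalies** ramp linearly between the midpoints of the base
  period (2007) and the mid-century window (2047); temperature anomalies
  are additive, precipitation anomalies multiplicative. The ramp is
  normalised so the *window-mean* difference between the two periods
  equals the configured annual deltas exactly, which makes the annual
  targets recoverable from the generated series to machine precision.
  Monsoon (June--October) and dry-season deltas are reconciled to the
  annual target by a common scale factor: with a single baseline
  climatology the annual and seasonal deltas of both worlds are mutually
  inconsistent, so the annual target takes precedence and the seasonal
  split is approximate (within a few percentage points). Daily weather
  noise (gamma-distributed, mean-preserving) is off by default so that
  scenario recovery is deterministic.
* **Cyclones** are independent homogeneous Poisson processes for strong
  (>= 140 km/h) and weak (80--140 km/h) classes with per-decade rates 0.4
  and 4.2, uniform landfall on the unit coastline, winds uniform within
  the class band, and a bimodal pre/post-monsoon seasonal timing typical
  of the Bay of Bengal. Sensitivity runs scale both intensities by 0.5 or
  1.5.
* **Population, economy, embankments, farming, land cover** are linear or
  compound-growth ramps over the 2015--2050 analysis window. Land-cover
  change is represented as a share-shift parameter (the cropland share of
  non-mangrove land at mid-century), a deliberate simplification of a
  narrative driver.

## Experiment design

`enumerate_runs()` builds the 62-run ensemble: 36 base scenarios (2
worlds x 2 sea-level levels x 3 cyclone sequences x 3 joint
socio-economic variants) plus 26 OAT runs, 13 per world: climate
(no-climate-change), sea-level rise (the other world's level), cyclone
frequency (x0.5 and x1.5), polder maintenance (the other regime), and for
each of population, economy, land cover and farming the two of {More
sustainable, Business as Usual, Less sustainable} that differ from the
parent world's own level. Where the source material gives two counts for
the additional simulations (24 and 26), the itemised enumeration (26,
consistent with 62 - 36) is implemented. Each run derives its seeds from
a master seed; cyclone sub-streams are shared across runs with the same
sequence number so OAT comparisons use common random numbers.

## Flood model and emulator

The reduced-form flood rule evaluates the annual maximum flood state per
union cell. The coastal water level is tide amplitude (default 1.0 m) +
relative sea level + the largest storm surge reaching the cell; surges
(3.0 m strong, 1.2 m weak at landfall) decay alongshore with a Gaussian
half-width of 0.25 coastline fractions and inland with an e-folding of
0.35 coast-distance units. A poldered cell floods when the water level
exceeds elevation + embankment height, an unprotected cell when it
exceeds elevation; depth is the positive excess. A fluvial/pluvial term
adds fractional inundation proportional to discharge x annual
precipitation excess above 1200 mm; the per-cell inundated fraction is
the maximum of the two mechanisms. Flood-water salinity is 25 dS/m at the
coast decaying inland (e-folding 0.4), and fresh (0.3 dS/m) for fluvial
water. These constants are free parameters (`flood_params()`): the
high-fidelity hydrodynamics they summarise is outside this model's scope.

The statistical emulator (`fit_emulator()`) combines partial least
squares (NIPALS) with canonical correlation analysis: inputs and outputs
are standardised, PLS extracts latent input scores, and a canonical
rotation aligns the score space with the output space before a
least-squares map to the outputs (the orthogonal complement of the
canonical variates is retained so no predictive direction is lost; with
zero components the emulator degenerates to the training output means).
Emulator inputs are *forcing summaries* (`flood_forcing_summaries()`):
sea level and its square — the overtopping threshold makes the response
convex in sea level — discharge, precipitation, and the fluvial forcing
product.

## Soil water and salt balance

Each union has a single root-zone bucket (the flux list, not the
discretisation, is the constraint; one bucket is the simplest scheme that
satisfies it). Daily:

```
W' = W + P + I + F_inf + C - ET - percolation - drainage
percolation = k_d * max(0, W - field-capacity store)
```

with porosity 0.45, field capacity 0.30, wilting point 0.10 (ET cannot
draw below it), drainage coefficient 0.15/day, capillary rise 0.3 mm/day
at salinity 10 dS/m at the coast (decaying inland, rising with sea
level), and 10% of standing flood depth infiltrating per day. Water above
saturation leaves as surface drainage. Salt is stored as mm x dS/m so
that EC = salt/water; salt enters with irrigation, infiltrated flood
water and capillary rise, and leaves with percolation (x leaching
efficiency 0.9) and surface drainage at the current concentration. Every
flux is returned so the water and salt ledgers can be audited; the test
suite closes both to 1e-9 each day. Root depth follows the crop calendar;
soil newly included when the zone deepens enters at field capacity with
capillary salinity, and both flows are book-kept explicitly.

The EC-to-salt conversion is linear with a configurable constant — only
relative salinity dynamics matter to the stress response.

## Crops

Two rice seasons are modelled: monsoon *aman* (sown mid-July) and
irrigated dry-season *boro* (sown early January), each with the standard
four-stage crop-coefficient curve. Reference evapotranspiration uses the
Blaney--Criddle form `ET0 = p (0.46 T + 8.13)` because the climate
generator produces daily mean temperature only; `p` comes from solar
geometry at latitude 22.5 N. Yield limitation multiplies four factors:

* water: FAO-33 linear response `1 - Ky (1 - ETa/ETm)` (Ky = 1.1);
* salinity: threshold--slope response, 1 up to the tolerance threshold
  then declining by 0.12 per dS/m (the rice threshold follows the
  scenario tolerance ramp);
* temperature: 1 inside 18--33 C, linear to 0 at 10 and 42 C, averaged
  daily over the season;
* flood: linear in the longest spell of standing water at or above
  0.5 m, reaching 0 at 5 days.

Multiplicative combination (rather than a minimum rule) was chosen for a
smooth sensitivity surface under OAT perturbations. Multi-season cropping
expands the boro area (0.4 to 0.8 of cropland) once the previous year's
region-mean dry-season water-stress factor exceeds 0.75 and the tolerance
ramp is active. Aquaculture is represented as a value add-on (25%) on
farm output rather than a separate crop; flood-tolerance parameters per
crop are placeholders, flagged in the configuration.

## Households

36 archetypes are built as 6 occupation-dominance types (farming, farm
labour, fishing, forest-goods collection, manufacturing, small business)
x 3 landholding classes (landless / small 0.4 ha / large 2 ha) x 2
income-mix variants. Population weights reproduce the region's published
marginal shares: ~56% functionally landless, >= 80% with agricultural
engagement, ~70% with mixed income sources. Landless households earn no
own-farm income (their farming share is redirected to farm labour).

Monthly income by source: own farming proportional to land and the farm
output value per hectare; farm labour capped by regional labour demand;
fishing and forest goods driven by static indices (forest goods are a
static input by assumption); manufacturing and small business scale with
the economic index.

When income cannot cover needs plus obligations, a coping plan is chosen
from a discrete action space (5 nonzero levels per action up to caps:
savings above a 500-unit floor, 25% of assets per month, a loan ceiling
of 2 monthly needs of outstanding debt, expenditure cuts up to 40%, up to
2 extra labouring members). The objective is lexicographic: achieve the
highest attainable tier (full needs met, then food need met), then
fewest labouring members, then fewest distinct coping actions, then
highest achieved expenditure; ties avoid loans, then asset sales, then
savings draws. "Financial capacity" is operationalised as achieved
expenditure relative to needs, the natural bounded measure given the
ledger. Safety nets (postponed loan repayment, then a friends-and-family
transfer up to 30% of needs) apply only when coping cannot meet full
needs. The discretisation makes the search exact and checkable against
exhaustive enumeration, which the test suite does on thousands of small
instances. A household is poor in a month when achieved expenditure falls
strictly below the upper poverty line (1800 per person-month by default;
the boundary convention is strict because the source material does not
state one), and hungry when it falls below the food need.

Cyclone shocks remove an absolute asset amount scaled by flood exposure;
an identical absolute shock removes a larger fraction of total wealth
from poorer households, which is the intended asymmetry.

## Indicators and analysis

Six indicators per run-year: inundated area (km2, annual maximum),
mean soil salinity (area-weighted mean of the annual per-union maximum,
dS/m), total rice production (t), poverty rate (%), Gini index and GDP
per capita. The Gini uses annual incomes (an expenditure-based variant is
a configuration choice; the income basis matches the indicator's
"income inequality" label). Poverty is the annual mean of monthly
population-weighted headcounts. Decadal values are means over 2041--2050
(the plotting horizon ends in 2050, so the last full decade is used) and
changes are taken against the 2005--2014 baseline.

Driver sensitivity collects the decadal changes across a driver's
settings (parent world + its OAT overrides), reports their range
(max - min), normalises per (indicator, world) by the largest range
across drivers — the normalisation is per indicator because the
normalised quantity is "actual/maximum" within each indicator's panel —
and categorises changes as low (<= 25%), moderate or high (>= 50%).

Poverty attribution by household group (farm-based / mixed / service x
landless / landed): the climatic contribution is the mean absolute
decadal deviation of the climatic OAT runs (climate, sea level,
cyclones) from the parent world, divided by the parent world's total
decadal poverty change against the baseline, clipped to [0, 1]; the
non-climatic share is its complement. The estimator is the
difference-vs-parent strategy; the extreme-year variant substitutes the
decade's maximum-poverty year for the decadal mean. Shares are undefined
(reported as missing) when the total change is zero.

## Synthetic region and calibration

`make_region()` generates union cells on a grid: areas ~26 km2 (+/-30%),
populations ~21,000, elevations 0--3 m falling toward the coast, 60%
poldered (concentrated in the low-lying coastal half) with 1.5 m design
embankments. `make_climatology()` provides a sinusoidal temperature cycle
(mean 26 C, amplitude 5 C) and monsoon-concentrated rainfall (2000 mm/yr,
80% in June--October via a von-Mises-shaped weight) with a discharge
index lagging rainfall by a month. These are stand-ins for external
forcing data and are configurable.

`calibrate_baseline()` finds a uniform income scaling by bisection so
that the simulated 2015 poverty rate matches a 27% target within 2
percentage points; needs are never scaled, preserving the expenditure
structure. Calibration uses a short simulation window ending in 2015.

What the generator does *not* emulate: the real union geography and
survey microdata, spatial correlation of weather, tides and storm-surge
hydrodynamics, groundwater flow, migration, and markets. Passing tests
therefore demonstrate internal consistency and mechanism-level
plausibility of the coupled system, not predictive skill for the real
delta. The study-scale headline outcomes (e.g. poverty reaching 17% vs
47% by 2050, salinity 6 to 7.6 dS/m) depend on calibrated high-fidelity
model libraries and survey data external to this package; the test suite
checks their *directions* (negative-world poverty and flooding exceed the
positive world; a drier monsoon leaves more salt in the soil) and logs
the desk-scale magnitudes without asserting them.

## Numerical choices and problem sizes

* 365-day calendar (no leap days); monsoon = June--October.
* Deterministic given (configuration, seed); the weather-noise and
  cyclone streams take explicit seeds, and OAT runs share sub-streams.
* Soil fluxes are evaluated in a fixed order (root-zone adjustment,
  inputs, ET with wilting floor, percolation, saturation overflow);
  concentrations divide by water bounded below at 1e-12 mm.
* The coping search space is a full discrete grid; lexicographic
  selection is by successive filtering, which is exact and
  order-deterministic.
* The test suite runs the integrated model at 16 unions, years
  2002--2050 for the ensemble checks and 2013--2015 for calibration;
  the default configuration is 64 unions over 1985--2050 with the first
  two decades as spin-up. The examples here are sized so the whole suite
  runs comfortably on a single CPU.

## Limitations

The flood rule has no hydrodynamics, sediment or erosion; soil has no
lateral flow or groundwater head; demography is a trajectory, not a
cohort model; migration and intra-household allocation are out of scope;
mangrove extent is static. The emulator is linear in its forcing
summaries and will underfit strongly thresholded responses unless the
summaries encode them (hence the squared sea-level term).
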