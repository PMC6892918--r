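---
title: "Model-based ideotype design with germplasm-specific trait distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based ideotype design with germplasm-specific trait distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ideotypr)
library(dplyr)
```

## The problem

Crop models let breeders ask "which combination of trait values would perform
best here?" before any cross is made: perturb the model parameters that
correspond to plant traits, simulate, and rank. The answer, however, depends
on *how far* each parameter is allowed to move. If the perturbation ranges
describe the species at large (literature compilations spanning continents
and decades of breeding), the resulting ideotype may be unreachable with the
genetic material actually in the program. This package implements the whole
ideotyping pipeline twice over — once with literature-derived distributions,
once with distributions measured on a specific germplasm — and quantifies
how much the recommendation changes.

The organism of reference is temperate japonica rice grown under potential
conditions (no water or nutrient limitation) in the Po valley; every stage
also accepts custom distributions, sites and scenarios.

## Trait distributions

Nine parameters define a candidate genotype (`trait_parameter_names()`):
radiation use efficiency (RUE, g MJ⁻¹), canopy light extinction coefficient
(k), specific leaf area at emergence and tillering (SLAini, SLAtill,
m² kg⁻¹), an ordinal blast-resistance class (1–3), and four threshold
temperatures (°C) for chalkiness, head-rice loss, cold- and heat-induced
spikelet sterility. The packaged sets (`germplasm_distributions()`,
`literature_distributions()`) differ in the four canopy/photosynthesis
traits and share the rest.

```{r}
germplasm_distributions() |> select(name, family, mean, sd, units)
```

Continuous traits are treated as independent normals. Independence is not an
approximation of convenience alone: on synthetic panels (and on the measured
panel the germplasm set encodes) the largest absolute pairwise Pearson
correlation is small and non-significant, which `pearson_correlations()`
lets you verify on any panel. A correlation structure could be injected by
replacing the quantile-mapping step of `sample_radial()`; the shipped
pipeline keeps the identity copula.

Fitting uses the sample mean and the n−1 standard deviation (`fit_normal()`,
minimum 3 varieties, zero-variance samples rejected). Distribution
comparison offers three branches (`ks_compare()`): two samples or a sample
against a fitted normal go through the asymptotic two-sided
Kolmogorov–Smirnov test — exact small-sample tables are deliberately not
implemented, since at panel size (n = 43) the asymptotic p-value is
adequate; two *theoretical* normals are compared by the closed-form
sup-difference of their CDFs on a refined grid, for which no p-value is
defined (`p_value = NA`).

## Field estimators

`estimate_rue()` converts stage measurements into RUE over the interval from
panicle initiation (BBCH 30) to late heading (BBCH 58) — a window chosen to
avoid both the open-canopy interception uncertainty of early growth and
senescence effects:

RUE = ΔAGB / (0.5 · ΣRAD · (1 − e^(−k·LAI))) / Tlim,

with ΔAGB stored in t ha⁻¹ and converted internally to g m⁻² (×100) so the
result is in g MJ⁻¹. `LAI` is the arithmetic mean of the two stage
measurements (a logarithmic mean is available via `lai_mean = "log"`; at
typical mid-season LAI the difference is negligible because interception is
nearly saturated). `Tlim` is the mean of a beta-type temperature response
with cardinals 12/28/38 °C and shape exponent c = 1 — the simplest member of
the family; the exponent is exposed (`temperature_response(shape =)`) since
only the cardinals, not the curvature, are well constrained.

The extinction coefficient comes from direct leaf-angle measurements through
the Campbell ellipsoidal leaf-angle distribution. The mean inclination
ᾱ (radians) relates to the ellipsoid shape parameter x through
ᾱ = 9.65·(3 + x)^(−1.65), inverted in `campbell_x_from_mean_angle()`; the
beam extinction coefficient is k = √(x² + tan²θ) / (x + 1.774·(x +
1.182)^(−0.733)) (`campbell_k()`). Because a single k per variety is wanted,
k is reported at one representative zenith angle, defaulting to 30°; the
convention the reference smartphone tooling uses is not documented, so the
angle is config-exposed and the default sits mid-morning for a summer
mid-latitude site. Diffuse-sky integration is out of scope.

## The WARM-lite simulator

`simulate_crop()` is a daily-step re-implementation of the processes a
net-photosynthesis rice model uses, built to be transparent and fast rather
than numerically faithful to any existing code base:

- **Phenology** (`develop()`): growing degree days above 12 °C map to a
  development stage DS (0 = emergence, 1 = flowering, 2 = maturity);
  defaults of 70/700/420 °C·day for sowing→emergence, emergence→flowering
  and flowering→maturity give a ~135-day cycle from mid-May sowing, in the
  range of Italian varieties. Phenology depends on weather and constants
  only — thermal-time requirements are not among the nine perturbed
  parameters — so one phenology run serves every genotype, which is what
  makes whole-design simulation cheap. Seasons too cold to mature are
  flagged (`complete = FALSE`), never raised as errors.
- **Growth**: ΔAGB = RUE · f(T) · f(CO2) · f(blast) · min(0.5·RAD·(1 −
  e^(−k·LAI)), cap). The PAR cap (10 MJ m⁻² d⁻¹) stands in for the
  saturation of the photosynthetic chain at high irradiance. f(CO2) is
  linear in the concentration above 360 ppm (8·10⁻⁴ ppm⁻¹, ≈ +7% at
  450 ppm). Partitioning to leaves and panicles follows piecewise-linear
  tables in DS — a deliberate simplification of the beta/parabolic curves
  full models use, whose coefficients are not public; the tables live in
  `model_constants()` and can be overridden. Leaf biomass becomes LAI
  through an SLA that ramps linearly from SLAini at emergence to SLAtill at
  tillering (DS 0.25) and stays constant after; LAI senesces at 1.5% per day
  per DS unit beyond flowering.
- **Blast** (`blast_pressure()`): a generic epidemic — daily infection
  pressure = temperature suitability (beta response, cardinals 10/22/32 °C)
  × leaf wetness proxy (RH ≥ 85% or rain) × class-specific rate, cumulated
  and saturated; the multiplier reduces RUE by at most 50%. **Class 3 is the
  most resistant** — the source material defines only "discrete (1, 2, 3)",
  so the polarity is stated here prominently and asserted in tests.
- **Sterility** (`spikelet_sterility()`): cold exceedances of Tmin below the
  genotype threshold during booting (DS 0.75–1.0) and heat exceedances of
  Tmax above the heat threshold during flowering (DS 0.96–1.06), each
  weighted by a Gaussian bell centred on its window (σ = window/4,
  representing the spread of culm development), passed through saturating
  per-degree-day responses (rate 0.08 °C⁻¹d⁻¹) and combined as
  1 − (1−cold)(1−heat).
- **Quality** (`grain_quality()`): chalkiness saturates with degree days of
  Tmean above the chalk threshold after heading; head rice decays with
  nighttime (Tmin) excess over the head-rice threshold and with wind and
  heavy-rain stress during grain fill.
- **Value** (`crop_value()`): yield × base price × quality multiplier. The
  price schedule (300 €/t, discount slopes 0.6 for chalkiness and 0.5 for
  head-rice loss) is invented plumbing: only its monotonicity matters to the
  science, and tests assert exactly that, never € magnitudes.

The simulator is a pure function of (genotype table, weather, constants,
CO2) — determinism is tested bit-for-bit. The hourly micrometeorology of
full models (mid-canopy and meristem temperatures) is simplified to daily
air temperature; the daily step with window-weighted stress accumulation is
the package's cost/fidelity compromise.

Defaults were calibrated once so that the mean germplasm genotype under
baseline Po-valley weather yields in the 6–12 t ha⁻¹ band observed for
high-input temperate rice (the 20-year fixture run gives ≈ 7.3 t ha⁻¹ with
AGB ≈ 18 t ha⁻¹, harvest index ≈ 0.4). A closure property ties the simulator
to the field estimator: running `simulate_crop(daily = TRUE)` under constant
optimal temperature and applying `estimate_rue()` to the simulated
biomass/LAI trajectory recovers the input RUE to well under 5% (the residual
comes from using the two-point mean LAI instead of the daily interception
integral).

## Synthetic weather and panels

`generate_weather()` replaces observed series and GCM downscaling with a
parametric generator (`site_climate()`): sinusoidal seasonal mean
temperature (13.2 °C annual mean, 10.5 °C half-amplitude, peak day 205) plus
AR(1) anomalies (ρ = 0.7, stationary sd 2.3 °C); radiation as the FAO-56
extraterrestrial envelope at 45.24° N times a stochastic transmissivity
(clear ≈ 0.68, wet ≈ 0.35); Bernoulli-gamma rain (wet-day probability 0.32,
gamma shape 0.75, scale 9 mm); humidity regimes by wet/dry day; log-normal
wind. These values describe a generic Po-valley rice season and were chosen
once from climate intuition, not tuned. What the generator does *not*
emulate: multi-day synoptic persistence beyond AR(1), seasonality of rain
frequency, heatwave clustering, and any correlation between temperature and
radiation anomalies other than through wet days. Passing tests on synthetic
weather therefore demonstrate the pipeline's internal consistency, not
climate realism.

Scenarios (`apply_scenario()`, `default_scenarios()`) are explicit
perturbations — additive temperature shift, fractional radiation change,
CO2 replacement — with rainfall untouched. The shipped table names RCP ×
GCM × timeframe combinations with *placeholder* deltas (documented as such);
studies about specific projections should supply their own.

`generate_panel()` draws synthetic variety panels (independent normals per
trait) for the four continuous field-measured traits; discrete traits are
refused by design, since panels represent measured phenotypes.

## Sensitivity analysis

`sample_radial()` builds the radial design: base matrix A (N points of a
scrambled Sobol' sequence in the unit hypercube, columns 10–18 of the same
sequence providing the independent matrix B) plus one AB_i block per
parameter, N(k+1) rows in total — 5120 at the canonical N = 512 for 9
parameters (> 500 × number of parameters). The package carries its own
Gray-code Sobol' generator (Joe–Kuo direction numbers, 20 dimensions,
verified against an independent reference implementation during
development) because no installed R package provides one; scrambling is a
seeded per-dimension digital shift, which preserves equidistribution —
the first 2^m points of every dimension stratify [0, 1) exactly, a property
the tests assert. Points are centred so u = 0 never occurs and normal
quantile mapping stays finite. A `scramble = FALSE` flag falls back to plain
pseudo-random points. Unit-cube coordinates map through each parameter's
inverse CDF; the 3-level discrete trait uses equal-probability thirds.

`total_order()` implements the Jansen estimator, the standard companion of
the radial design: ST_i = mean[(f(A) − f(AB_i))²] / (2·V̂), V̂ the sample
variance over the A rows. Negative estimates (Monte Carlo noise around zero)
are clipped to 0 for ranking but reported raw (`st_raw`). Rankings break
ties alphabetically — TDCC requires a total order, and the tie-break is
deterministic and documented. The output variable is the per-hectare value
averaged over all simulated years of a scenario (switchable to yield),
and one design per distribution set is reused across scenarios — cheaper and
variance-reducing, at the cost of correlated scenario estimates, which is
acceptable because scenarios are compared qualitatively.

`tdcc()` implements the Savage-score concordance; its tests include a
brute-force oracle over all 120 rankings of 5 items and a hand-computed
reversed-ranking case (−0.9286 at n = 3).

## Ideotype scoring

`ideotype_score()` ranks combinations ascending — both desirable conditions
(all traits at their means; best value) drive the score to zero, so *lower
is better*; this convention is stated explicitly because the score's
structure admits either reading. Indices below 1e-4 are floored before the
1/√S weighting so that parameters with null sensitivity do not dominate the
feasibility term. `derive_profile()` averages the top ⌈fraction·rows⌉
combinations (minimum 1; default fraction 1%) — averaging smooths over
local minima of the parameter space; the discrete blast class is averaged
and rounded to the nearest level. Y in the score is the multi-year mean
value per combination (a single output per combination), not a per-year
quantity aggregated afterwards.

`yield_benefit()` compares the profile genotype to the genotype at the
distribution means, year by year on shared weather, reporting mean ± sd of
the relative benefit across years; years where the mean genotype produces
nothing are excluded with a warning.

## The study harness

`run_study()` ties it together: one weather series per study (shared across
arms so the comparison isolates the distributions), one design seed shared
across arms (the unit-cube points coincide; only the quantile mapping
differs — a variance-reducing pairing), per-stage seeds derived from the
master seed by fixed offsets (`derive_seed()`), and a report containing
per-arm/per-scenario indices, rankings, profiles, benefits, cross-arm TDCC
per scenario and averaged. `write_study_report()` persists everything as
CSV/JSON plus a manifest. Determinism is bit-for-bit and tested. The
package's interface is its exported functions; studies are composed in R
scripts rather than through a shell entry point.

## Problem sizes and limitations

The shipped tests and the acceptance script run the pipeline at desk scale:
base designs of 64–1024 points, 2–5 years of weather for design evaluation
(20 years for single-genotype agronomy checks), and 20 replicate master
seeds for the two-arm comparison. At these sizes the qualitative claims are
stable — the germplasm set's wider RUE distribution (sd 0.23 vs 0.09)
raises RUE's total-order index above the literature arm's in every replicate
seed, and cross-arm concordance stays well below 1 — but individual index
values carry Monte Carlo noise of a few points.

Known limitations: no water or nitrogen limitation (potential-conditions
management only); daily time step without intra-canopy microclimate; a
single generic blast coupling (no leaf/neck distinction); invented economic
constants; placeholder scenario deltas; and a weather generator that is
deliberately simpler than a calibrated stochastic downscaler. None of these
affect the package's purpose — quantifying how distribution choice
propagates through an otherwise fixed ideotyping pipeline — but absolute
yields, values and index magnitudes should not be read as predictions for
any real site.
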