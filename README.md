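# ideotypr

Model-based crop ideotype design in R, with a focus on how the *choice of
trait-parameter distributions* — measured on the germplasm actually available
to a breeding program versus compiled from the literature — changes which
traits a simulation study tells breeders to improve.

The package is written for crop modellers and quantitative breeders. It
covers the full pipeline:

1. **Trait distributions** — fit normal distributions to phenotyped variety
   panels, test normality (Shapiro–Wilk), compare distributions
   (Kolmogorov–Smirnov), and test trait independence (Pearson). Two canonical
   nine-parameter rice sets ship with the package: a germplasm-specific set
   (RUE, k, SLAini, SLAtill measured on a 43-variety Italian panel) and a
   literature-derived set, sharing five stress/quality parameters.
2. **Field estimators** — radiation use efficiency from stage biomass and
   intercepted PAR, the canopy extinction coefficient from measured leaf
   angles via the Campbell ellipsoidal distribution, and specific leaf area.
3. **WARM-lite** — a simplified daily rice growth-and-quality simulator:
   net-photosynthesis RUE approach with Lambert–Beer light interception,
   development-stage-driven partitioning and SLA, a generic blast epidemic,
   cold/heat spikelet sterility, chalkiness and head rice, and a per-hectare
   value combining yield and quality.
4. **Synthetic environments** — a stochastic daily weather generator with
   Po-valley-like seasonality, configurable climate-scenario perturbations
   (temperature shift, radiation scaling, CO2), and synthetic germplasm
   panels, so every stage runs without external data.
5. **Sensitivity analysis and ideotypes** — radial Sobol' sampling of the
   nine-parameter space, Jansen total-order indices, Savage-score rank
   concordance (TDCC), an ideotype score, top-1% profile averaging, and
   benefit quantification against the mean genotype.

## The statistics at the core

**Radiation use efficiency from field data.** Over the interval between
panicle initiation (BBCH 30) and late heading (BBCH 58),

```
RUE = ΔAGB / (0.5 · ΣRAD · (1 − exp(−k · LAI_mean))) / Tlim
```

with ΔAGB the biomass increment (g m⁻²), ΣRAD the cumulated global radiation
(MJ m⁻²), 0.5 the global-to-PAR conversion, `k` the extinction coefficient,
and `Tlim` the mean beta-type thermal limitation with cardinal temperatures
12/28/38 °C.

**Total-order sensitivity.** On a radial design (base matrix A of N points
plus, per parameter i, a matrix AB_i with column i resampled; N·(k+1) rows,
5120 for N = 512 and k = 9), the Jansen estimator

```
ST_i = mean[(f(A) − f(AB_i))²] / (2 · Var f(A))
```

ranks parameters by the share of output variance (per-hectare value) they
control, interactions included.

**Ideotype score.** Each sampled combination x is scored

```
I = [ Σ_i (100·|x_i − m_i|/m_i) / √S_i / n ] · (1 − Y/Y_max)
```

(lower is better): deviations from the distribution means m are discounted
by the trait's total-order index S, and the whole is scaled by the shortfall
from the best value Y_max. The ideotype profile averages the parameter
values of the top 1% of combinations.

**Rank concordance.** Rankings from different distribution sets are compared
with the top-down concordance coefficient built on Savage scores
`SS(r) = Σ_{j=r..n} 1/j`, which weights agreement among top-ranked traits
most heavily.

## Worked example

A small two-arm study (base design 128 → 1280 combinations, 5 years of
synthetic baseline weather):

```r
library(ideotypr)

cfg <- study_config(
  base_n = 128, years = 5, seed = 2025,
  scenarios = default_scenarios("baseline")
)
report <- run_study(cfg)
report
#> Ideotyping study: 2 arm(s) x 1 scenario(s), base_n = 128 (1280 combinations), 5 weather year(s), seed 2025
#>   [germplasm | baseline] top parameter: RUE (ST = 0.538)
#>   [literature | baseline] top parameter: T-ColdSter (ST = 0.388)
#>   average TDCC across arm pairs and scenarios: 0.613
```

Under the germplasm-specific distributions (RUE sd 0.23 instead of the
literature's 0.09) radiation use efficiency becomes the dominant parameter;
with the literature set it is overtaken by stress-threshold parameters — the
rankings agree only partially (TDCC 0.613, well below 1). The ideotype
profiles reflect the same shift:

```r
dplyr::filter(report$profiles, parameter %in% c("RUE", "k", "SLAtill"))
#>   arm        scenario parameter  value  mean deviation_pct
#> 1 germplasm  baseline RUE        3.21   2.72        18.1
#> 2 germplasm  baseline k          0.556  0.58        -4.13
#> 3 germplasm  baseline SLAtill   28.2   28.7         -1.59
#> 4 literature baseline RUE        2.85   2.68         6.43
#> 5 literature baseline k          0.466  0.47        -0.847
#> 6 literature baseline SLAtill   29.0   28.7          1.23
```

The germplasm arm proposes a much larger RUE improvement (+18% vs +6%)
because the measured panel actually contains that variability. Per-module
entry points (`fit_normal()`, `ks_compare()`, `estimate_rue()`,
`campbell_k()`, `simulate_crop()`, `sample_radial()`, `total_order()`,
`tdcc()`, `derive_profile()`, `yield_benefit()`) compose with pipes, return
tibbles, and have `tidy()`, `glance()` and `autoplot()` methods where a
result object is involved.

## Documentation

The methods vignette (`vignettes/ideotype-design.Rmd`) describes the model,
its assumptions, every tunable constant, what the synthetic generators do
and do not emulate, and the package's numerical and design choices.
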