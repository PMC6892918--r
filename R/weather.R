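# Stochastic daily weather generation with Po-valley-like seasonality, and
# climate-scenario perturbation. Stands in for observed multi-year series and
# GCM downscaling: scenarios are explicit additive/multiplicative deltas.

#' Site climate parameters for the weather generator
#'
#' Parametric description of a site's climate: sinusoidal seasonal mean
#' temperature with AR(1) day-to-day anomalies, clear-sky radiation envelope
#' (extraterrestrial radiation at the site latitude times a stochastic
#' transmissivity), Bernoulli-gamma rainfall, humidity regimes for wet and
#' dry days, and log-normal wind. Defaults emulate a rice site in the
#' Po valley, Northern Italy (45.24 N).
#'
#' @param lat Latitude, degrees north.
#' @param t_annual_mean Annual mean temperature, degC.
#' @param t_amplitude Seasonal half-amplitude of daily mean temperature, degC.
#' @param t_peak_doy Day of year of the warmest day.
#' @param t_daily_sd Stationary sd of daily temperature anomalies, degC.
#' @param ar1 AR(1) coefficient of the anomaly process, in (-1, 1).
#' @param diurnal_base,diurnal_clear Diurnal temperature range, degC: base
#'   plus a clear-sky-proportional term.
#' @param p_wet Probability that a day is wet.
#' @param rain_shape,rain_scale Gamma parameters of wet-day rainfall, mm.
#' @param tau_clear,tau_wet Mean atmospheric transmissivity on dry and wet
#'   days; `tau_sd` its day-to-day sd.
#' @param tau_sd See `tau_clear`.
#' @param rh_wet_mean,rh_wet_sd,rh_dry_mean,rh_dry_sd Relative humidity
#'   regimes, percent.
#' @param wind_meanlog,wind_sdlog Log-normal wind speed parameters, m/s.
#' @param start_year First calendar year of generated series.
#' @return A named list of class `site_climate`.
#' @export
site_climate <- function(lat = 45.24, t_annual_mean = 13.2, t_amplitude = 10.5,
                         t_peak_doy = 205, t_daily_sd = 2.3, ar1 = 0.7,
                         diurnal_base = 8, diurnal_clear = 5,
                         p_wet = 0.32, rain_shape = 0.75, rain_scale = 9,
                         tau_clear = 0.68, tau_wet = 0.35, tau_sd = 0.07,
                         rh_wet_mean = 88, rh_wet_sd = 5,
                         rh_dry_mean = 62, rh_dry_sd = 10,
                         wind_meanlog = log(2), wind_sdlog = 0.45,
                         start_year = 2001) {
  stopifnot(
    t_amplitude > 0, p_wet >= 0, p_wet <= 1, abs(ar1) < 1,
    tau_clear > 0, tau_clear < 1, tau_wet > 0, tau_wet < 1
  )
  structure(as.list(environment()), class = "site_climate")
}

# FAO-56 extraterrestrial radiation, MJ/m2/day
.extraterrestrial_radiation <- function(doy, lat_deg) {
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Generate a multi-year synthetic daily weather series
#'
#' Daily minimum/maximum temperature, global radiation, rainfall, relative
#' humidity and wind for `years` whole calendar years at a parametric site.
#' Temperature is a seasonal sinusoid plus AR(1) anomalies; radiation is the
#' extraterrestrial envelope scaled by a stochastic transmissivity (lower on
#' wet days); rainfall is Bernoulli-gamma. The series is reproducible given
#' `seed` and carries a `co2` attribute (reference concentration) consumed by
#' [simulate_crop()].
#'
#' @param site A [site_climate()] list.
#' @param years Number of calendar years (>= 1).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param co2 CO2 concentration attached to the series, ppm.
#' @return A tibble with columns `date`, `tmin`, `tmax`, `rad`, `rain`,
#'   `rh`, `wind` and attribute `co2`.
#' @examples
#' w <- generate_weather(site_climate(), years = 1, seed = 42)
#' @export
generate_weather <- function(site = site_climate(), years, seed, co2 = 360) {
  if (years < 1) rlang::abort("`years` must be >= 1.")
  dates <- seq(
    as.Date(sprintf("%d-01-01", site$start_year)),
    as.Date(sprintf("%d-12-31", site$start_year + years - 1)),
    by = "day"
  )
  n <- length(dates)
  doy <- as.integer(strftime(dates, "%j"))
  t_season <- site$t_annual_mean +
    site$t_amplitude * cos(2 * pi * (doy - site$t_peak_doy) / 365.25)
  draws <- withr::with_seed(as.integer(seed), {
    eps_sd <- site$t_daily_sd * sqrt(1 - site$ar1^2)
    anom <- as.numeric(
      stats::filter(stats::rnorm(n, 0, eps_sd), site$ar1, method = "recursive")
    )
    wet <- stats::rbinom(n, 1, site$p_wet)
    tau <- ifelse(wet == 1, site$tau_wet, site$tau_clear) +
      stats::rnorm(n, 0, site$tau_sd)
    rain <- wet * stats::rgamma(n, shape = site$rain_shape, scale = site$rain_scale)
    rh <- ifelse(wet == 1,
      stats::rnorm(n, site$rh_wet_mean, site$rh_wet_sd),
      stats::rnorm(n, site$rh_dry_mean, site$rh_dry_sd)
    )
    wind <- stats::rlnorm(n, site$wind_meanlog, site$wind_sdlog)
    list(anom = anom, tau = tau, rain = rain, rh = rh, wind = wind)
  })
  tmean <- t_season + draws$anom
  tau <- pmin(pmax(draws$tau, 0.08), 0.78)
  rad <- .extraterrestrial_radiation(doy, site$lat) * tau
  range_c <- site$diurnal_base + site$diurnal_clear * tau / 0.75
  rain <- draws$rain
  rh <- pmin(pmax(draws$rh, 25), 100)
  wind <- draws$wind

  out <- tibble::tibble(
    date = dates,
    tmin = tmean - range_c / 2,
    tmax = tmean + range_c / 2,
    rad = rad, rain = rain, rh = rh, wind = wind
  )
  attr(out, "co2") <- co2
  out
}

#' Apply a climate scenario to a weather series
#'
#' Shifts temperatures additively by `delta_t`, scales radiation by
#' `(1 + delta_rad)`, and replaces the CO2 attribute; rainfall, humidity and
#' wind are untouched and the series length is preserved.
#'
#' @param weather A weather tibble from [generate_weather()] or
#'   [read_weather_csv()].
#' @param scenario Optional one-row tibble with columns `delta_t`,
#'   `delta_rad`, `co2` (e.g. a row of [default_scenarios()]); alternatively
#'   give the three values directly.
#' @param delta_t Additive temperature shift, degC.
#' @param delta_rad Fractional radiation change.
#' @param co2 New CO2 concentration, ppm.
#' @return The perturbed weather tibble.
#' @export
apply_scenario <- function(weather, scenario = NULL, delta_t = 0,
                           delta_rad = 0, co2 = NULL) {
  .check_weather(weather)
  if (!is.null(scenario)) {
    stopifnot(nrow(scenario) == 1L)
    delta_t <- scenario$delta_t
    delta_rad <- scenario$delta_rad
    co2 <- scenario$co2
  }
  out <- weather
  out$tmin <- out$tmin + delta_t
  out$tmax <- out$tmax + delta_t
  out$rad <- out$rad * (1 + delta_rad)
  attr(out, "co2") <- co2 %||% attr(weather, "co2")
  out
}

#' Packaged climate-scenario table
#'
#' Baseline plus perturbation scenarios named after RCP x GCM combinations
#' for the 2030 and 2050 timeframes. The temperature/radiation deltas and
#' CO2 concentrations are plausible placeholder values (the package performs
#' no GCM downscaling); edit the returned tibble or supply your own to
#' define different scenarios.
#'
#' @param timeframes Subset of `c("baseline", "2030", "2050")` to return.
#' @return A tibble with columns `label`, `timeframe`, `delta_t`,
#'   `delta_rad`, `co2`.
#' @export
default_scenarios <- function(timeframes = c("baseline", "2030")) {
  path <- system.file("extdata", "scenarios.csv",
    package = "ideotypr", mustWork = TRUE
  )
  out <- readr::read_csv(path, show_col_types = FALSE)
  out[out$timeframe %in% timeframes, ]
}

#' Read or write a daily weather CSV
#'
#' One row per day with header
#' `date,tmin_c,tmax_c,rad_mj_m2,rain_mm,rh_pct,wind_m_s`.
#'
#' @param path File path.
#' @param weather Weather tibble.
#' @param co2 CO2 attribute to attach on read, ppm.
#' @return The weather tibble, or `path` invisibly for the writer.
#' @export
read_weather_csv <- function(path, co2 = 360) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble::tibble(
    date = as.Date(raw$date), tmin = raw$tmin_c, tmax = raw$tmax_c,
    rad = raw$rad_mj_m2, rain = raw$rain_mm, rh = raw$rh_pct,
    wind = raw$wind_m_s
  )
  attr(out, "co2") <- co2
  .check_weather(out)
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  .check_weather(weather)
  readr::write_csv(
    tibble::tibble(
      date = weather$date, tmin_c = weather$tmin, tmax_c = weather$tmax,
      rad_mj_m2 = weather$rad, rain_mm = weather$rain, rh_pct = weather$rh,
      wind_m_s = weather$wind
    ),
    path
  )
  invisible(path)
}

#' Generate a synthetic germplasm trait panel
#'
#' Draws a variety panel from the normal trait distributions of a set:
#' independent draws per trait (the packaged sets found no significant trait
#' correlations), emulating a phenotyping experiment of `n_varieties`
#' varieties. Discrete traits cannot be requested: panels hold measured
#' continuous traits only.
#'
#' @param dset A distribution set containing the requested traits.
#' @param n_varieties Panel size (>= 3).
#' @param seed Integer seed.
#' @param traits Trait names to draw; defaults to the four field-measured
#'   canopy/photosynthesis traits.
#' @return A tibble with a `variety` column and one column per trait.
#' @examples
#' generate_panel(germplasm_distributions(), 43, seed = 1)
#' @export
generate_panel <- function(dset, n_varieties = 43, seed,
                           traits = c("RUE", "k", "SLAini", "SLAtill")) {
  if (n_varieties < 3) rlang::abort("`n_varieties` must be >= 3.")
  idx <- match(traits, dset$name)
  if (anyNA(idx)) {
    rlang::abort(paste0(
      "traits absent from the set: ",
      paste(traits[is.na(idx)], collapse = ", ")
    ))
  }
  if (any(dset$family[idx] != "normal")) {
    rlang::abort("panels hold measured continuous traits only; discrete traits cannot be drawn.")
  }
  draws <- withr::with_seed(as.integer(seed), {
    purrr::map(idx, function(i) {
      stats::rnorm(n_varieties, dset$mean[i], dset$sd[i])
    })
  })
  names(draws) <- traits
  dplyr::bind_cols(
    tibble::tibble(variety = sprintf("V%03d", seq_len(n_varieties))),
    tibble::as_tibble(draws)
  )
}
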