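# WARM-style daily rice simulator: net-photosynthesis RUE approach,
# Lambert-Beer interception, DS-driven partitioning and SLA, generic blast
# epidemic, cold/heat spikelet sterility, chalkiness and head rice, and a
# price-based per-hectare value.

.weather_cols <- c("date", "tmin", "tmax", "rad", "rain", "rh", "wind")

.check_weather <- function(weather) {
  missing <- setdiff(.weather_cols, names(weather))
  if (length(missing)) {
    rlang::abort(paste0("weather lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(weather$rad < 0)) rlang::abort("negative radiation in weather series.")
  if (any(weather$tmin > weather$tmax)) rlang::abort("tmin > tmax in weather series.")
  invisible(weather)
}

#' Thermal-time phenology of a rice season
#'
#' Accumulates growing degree days above the development base temperature
#' from the sowing day and maps them to a continuous development stage
#' (DS = 0 at emergence, 1 at flowering, 2 at maturity), anchoring the
#' BBCH-like stage dates used downstream (tillering, panicle initiation,
#' heading, flowering, maturity). Phenology is driven by weather and model
#' constants only, not by the perturbed genotype parameters.
#'
#' @param weather_year Daily weather tibble for one calendar year.
#' @param constants A [model_constants()] list.
#' @return A tibble with one row per day from sowing to the end of the year:
#'   `date`, `doy`, `tmean`, `ds` (NA before emergence, capped at 2), with
#'   attributes `stages` (named list of stage dates) and `complete` (logical;
#'   `FALSE` flags a season too cold to reach maturity).
#' @export
develop <- function(weather_year, constants = model_constants()) {
  .check_weather(weather_year)
  doy <- as.integer(strftime(weather_year$date, "%j"))
  season <- weather_year[doy >= constants$sowing_doy, ]
  if (nrow(season) == 0L) rlang::abort("weather does not cover the season from sowing.")
  tmean <- (season$tmin + season$tmax) / 2
  gdd <- pmax(0, tmean - constants$t_base_dev)
  cum <- cumsum(gdd)

  i_em <- which(cum >= constants$gdd_emergence)[1]
  ds <- rep(NA_real_, nrow(season))
  stages <- list(
    sowing = season$date[1], emergence = as.Date(NA), tillering = as.Date(NA),
    panicle_initiation = as.Date(NA), heading = as.Date(NA),
    flowering = as.Date(NA), maturity = as.Date(NA)
  )
  complete <- FALSE
  if (!is.na(i_em)) {
    stages$emergence <- season$date[i_em]
    # thermal time accumulated after emergence
    g2 <- cum - cum[i_em]
    g2[seq_len(i_em)] <- 0
    gf <- constants$gdd_flowering
    gm <- constants$gdd_maturity
    ds_raw <- ifelse(g2 <= gf, g2 / gf, 1 + (g2 - gf) / gm)
    ds[i_em:nrow(season)] <- pmin(ds_raw[i_em:nrow(season)], 2)
    stage_date <- function(level) {
      i <- which(!is.na(ds) & ds >= level)[1]
      if (is.na(i)) as.Date(NA) else season$date[i]
    }
    stages$tillering <- stage_date(constants$ds_tillering)
    stages$panicle_initiation <- stage_date(constants$ds_panicle_init)
    stages$heading <- stage_date(constants$ds_heading)
    stages$flowering <- stage_date(1)
    stages$maturity <- stage_date(2)
    complete <- !is.na(stages$maturity)
  }
  out <- tibble::tibble(
    date = season$date, doy = doy[doy >= constants$sowing_doy],
    tmean = tmean, ds = ds
  )
  attr(out, "stages") <- stages
  attr(out, "complete") <- complete
  out
}

#' Daily blast-disease multiplier series
#'
#' Generic airborne-epidemic severity index: daily infection pressure is the
#' product of a beta-type temperature suitability and a leaf-wetness proxy
#' (RH above a threshold or a rainy day), scaled by a resistance-class
#' infection rate; cumulated pressure saturates into a severity in \[0, 1)
#' and the returned multiplier `1 - max_impact * severity` reduces radiation
#' use efficiency. Class 3 is the most resistant.
#'
#' @param weather_year Daily weather rows covering the period of interest.
#' @param blast_res Resistance class, integer in \{1, 2, 3\}.
#' @inheritParams develop
#' @return Numeric vector (one multiplier per input day) in (0, 1].
#' @export
blast_pressure <- function(weather_year, blast_res,
                           constants = model_constants()) {
  .check_weather(weather_year)
  blast_res <- as.integer(blast_res)
  if (length(blast_res) != 1L || !blast_res %in% 1:3) {
    rlang::abort("`blast_res` must be a single class in {1, 2, 3}.")
  }
  tmean <- (weather_year$tmin + weather_year$tmax) / 2
  suit <- temperature_response(tmean, constants$blast_cardinals)
  wet <- as.numeric(weather_year$rh >= constants$blast_rh_threshold |
    weather_year$rain > 1)
  pressure <- cumsum(constants$blast_rate[blast_res] * suit * wet)
  severity <- 1 - exp(-pressure)
  1 - constants$blast_max_impact * severity
}

.bell_weights <- function(ds, window) {
  mid <- mean(window)
  sigma <- diff(window) / 4
  w <- exp(-0.5 * ((ds - mid) / sigma)^2)
  w[is.na(ds) | ds < window[1] | ds > window[2]] <- 0
  w
}

# degree-day accumulation of `temp` beyond genotype thresholds, weighted by
# a DS-centred bell; rows = days, columns = genotypes
.weighted_excess <- function(temp, weights, thresholds, direction) {
  active <- which(weights > 0)
  if (length(active) == 0L) {
    return(rep(0, length(thresholds)))
  }
  exc <- if (direction == "above") {
    pmax(outer(temp[active], thresholds, "-"), 0)
  } else {
    pmax(-outer(temp[active], thresholds, "-"), 0)
  }
  as.numeric(crossprod(exc, weights[active]))
}

#' Cold- and heat-induced spikelet sterility
#'
#' Cold sterility accumulates from pre-flowering (booting) days whose minimum
#' temperature falls below the genotype cold threshold; heat sterility from
#' flowering days whose maximum exceeds the heat threshold. Daily exceedances
#' are weighted by a Gaussian bell centred on each window (accounting for
#' heterogeneity in culm development), converted through a saturating
#' per-degree-day response, and combined as
#' `1 - (1 - cold) * (1 - heat)`.
#'
#' @param weather_year Daily weather rows for the season.
#' @param ds Development-stage series aligned with `weather_year` rows
#'   (from [develop()]).
#' @param t_coldster,t_heatster Genotype threshold temperatures, degC
#'   (vectors of equal length for many genotypes at once).
#' @inheritParams develop
#' @return Sterility fraction in \[0, 1\], one per genotype.
#' @export
spikelet_sterility <- function(weather_year, ds, t_coldster, t_heatster,
                               constants = model_constants()) {
  .check_weather(weather_year)
  if (length(ds) != nrow(weather_year)) {
    rlang::abort("`ds` must align with `weather_year` rows.")
  }
  w_cold <- .bell_weights(ds, constants$cold_window_ds)
  w_heat <- .bell_weights(ds, constants$heat_window_ds)
  cold_dd <- .weighted_excess(weather_year$tmin, w_cold, t_coldster, "below")
  heat_dd <- .weighted_excess(weather_year$tmax, w_heat, t_heatster, "above")
  cold <- 1 - exp(-constants$cold_rate * cold_dd)
  heat <- 1 - exp(-constants$heat_rate * heat_dd)
  1 - (1 - cold) * (1 - heat)
}

#' Chalkiness and head-rice fractions
#'
#' Chalkiness grows with degree days of mean temperature above the genotype
#' chalkiness threshold accumulated after heading, through a saturating
#' exponential response. Head rice (fraction of kernels surviving milling
#' whole) decays exponentially with nighttime-temperature excess over the
#' head-rice threshold during grain filling and with wind and heavy-rain
#' stress terms.
#'
#' @inheritParams spikelet_sterility
#' @param t_chalk,t_headrice Genotype threshold temperatures, degC (vectors).
#' @return A list with numeric vectors `chalkiness` and `head_rice`, both in
#'   \[0, 1\], one element per genotype.
#' @export
grain_quality <- function(weather_year, ds, t_chalk, t_headrice,
                          constants = model_constants()) {
  .check_weather(weather_year)
  if (length(ds) != nrow(weather_year)) {
    rlang::abort("`ds` must align with `weather_year` rows.")
  }
  fill <- !is.na(ds) & ds >= constants$ds_heading & ds <= 2
  w <- as.numeric(fill)
  tmean <- (weather_year$tmin + weather_year$tmax) / 2
  chalk_dd <- .weighted_excess(tmean, w, t_chalk, "above")
  night_dd <- .weighted_excess(weather_year$tmin, w, t_headrice, "above")
  wind_stress <- sum(pmax(0, weather_year$wind[fill] - constants$wind_threshold))
  rain_stress <- sum(pmax(0, weather_year$rain[fill] - constants$rain_threshold))
  chalkiness <- 1 - exp(-constants$chalk_rate * chalk_dd)
  head_rice <- exp(-(constants$headrice_rate * night_dd +
    constants$wind_rate * wind_stress +
    constants$rain_rate * rain_stress))
  list(chalkiness = chalkiness, head_rice = pmin(pmax(head_rice, 0), 1))
}

#' Per-hectare crop value
#'
#' `value = yield * base_price * (1 - chalk_discount * chalkiness) *
#' (1 - headrice_discount * (1 - head_rice))`: monotone decreasing in
#' chalkiness, increasing in head rice, equal to `yield * base_price` for
#' perfect quality.
#'
#' @param yield Paddy yield, t/ha (vectorised).
#' @param chalkiness,head_rice Quality fractions in \[0, 1\].
#' @inheritParams develop
#' @return Value in euro/ha.
#' @export
crop_value <- function(yield, chalkiness, head_rice,
                       constants = model_constants()) {
  if (any(chalkiness < 0 | chalkiness > 1) || any(head_rice < 0 | head_rice > 1)) {
    rlang::abort("quality fractions must lie in [0, 1].")
  }
  mult <- (1 - constants$chalk_discount * chalkiness) *
    (1 - constants$headrice_discount * (1 - head_rice))
  pmax(0, yield) * constants$base_price * mult
}

.check_params <- function(params) {
  gcols <- unname(.param_cols)
  missing <- setdiff(gcols, names(params))
  if (length(missing)) {
    rlang::abort(paste0("genotype table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  cont <- setdiff(gcols, "blast_res")
  if (any(vapply(params[cont], function(x) any(!is.finite(x) | x <= 0), logical(1)))) {
    rlang::abort("continuous crop parameters must be finite and positive.")
  }
  if (!all(params$blast_res %in% 1:3)) {
    rlang::abort("`blast_res` must take values in {1, 2, 3}.")
  }
  invisible(params)
}

# One year's growth for all genotypes at once (vectors over genotypes).
.simulate_year <- function(params, weather_year, constants, co2,
                           daily = FALSE) {
  dev <- develop(weather_year, constants)
  stages <- attr(dev, "stages")
  complete <- attr(dev, "complete")
  G <- nrow(params)
  zero <- function() {
    tibble::tibble(
      genotype = params$genotype, year = as.integer(strftime(weather_year$date[1], "%Y")),
      yield = 0, agb = 0, sterility = NA_real_, chalkiness = NA_real_,
      head_rice = NA_real_, value = 0,
      flowering = stages$flowering, maturity = stages$maturity,
      complete = FALSE
    )
  }
  if (is.na(stages$emergence)) {
    return(zero())
  }
  season_w <- weather_year[weather_year$date >= dev$date[1], ]
  grow <- which(!is.na(dev$ds))
  if (!is.na(stages$maturity)) {
    grow <- grow[dev$date[grow] <= stages$maturity]
  }
  ds_g <- dev$ds[grow]
  ft <- temperature_response(dev$tmean[grow], constants$cardinals, constants$beta_shape)
  fco2 <- max(0, 1 + constants$co2_slope * (co2 - constants$co2_ref))
  rad <- season_w$rad[grow]
  lfrac <- stats::approx(constants$partition_leaf$ds, constants$partition_leaf$frac,
    xout = ds_g, rule = 2
  )$y
  pfrac <- stats::approx(constants$partition_panicle$ds, constants$partition_panicle$frac,
    xout = ds_g, rule = 2
  )$y
  classes <- sort(unique(params$blast_res))
  bmult <- matrix(1, nrow = length(grow), ncol = 3)
  for (cl in classes) {
    bmult[, cl] <- blast_pressure(season_w[grow, ], cl, constants)
  }

  rue <- params$rue
  k <- params$k
  sla_ini <- params$sla_ini
  sla_till <- params$sla_till
  cls <- params$blast_res
  agb <- rep(constants$agb_ini, G)
  lai <- constants$agb_ini * 0.1 * lfrac[1] * sla_ini
  pan <- rep(0, G)
  if (daily) {
    agb_track <- matrix(NA_real_, length(grow), G)
    lai_track <- matrix(NA_real_, length(grow), G)
  }
  for (d in seq_along(grow)) {
    fint <- 1 - exp(-k * lai)
    ipar <- pmin(0.5 * rad[d] * fint, constants$sat_ipar)
    dagb <- rue * ft[d] * fco2 * bmult[d, cls] * ipar * 0.01 # t/ha
    agb <- agb + dagb
    pan <- pan + pfrac[d] * dagb
    ramp <- min(ds_g[d] / constants$ds_tillering, 1)
    sla_d <- sla_ini + (sla_till - sla_ini) * ramp
    lai <- lai + lfrac[d] * dagb * 0.1 * sla_d
    if (ds_g[d] > 1) {
      lai <- lai * (1 - constants$senescence_rate * (ds_g[d] - 1))
    }
    if (daily) {
      agb_track[d, ] <- agb
      lai_track[d, ] <- lai
    }
  }

  ster <- spikelet_sterility(
    season_w, dev$ds, params$t_coldster, params$t_heatster, constants
  )
  qual <- grain_quality(
    season_w, dev$ds, params$t_chalk, params$t_headrice, constants
  )
  yield <- pan * (1 - ster)
  value <- crop_value(yield, qual$chalkiness, qual$head_rice, constants)
  out <- tibble::tibble(
    genotype = params$genotype,
    year = as.integer(strftime(weather_year$date[1], "%Y")),
    yield = yield, agb = agb, sterility = ster,
    chalkiness = qual$chalkiness, head_rice = qual$head_rice, value = value,
    flowering = stages$flowering, maturity = stages$maturity,
    complete = complete
  )
  if (daily) {
    attr(out, "daily") <- tibble::tibble(
      genotype = rep(params$genotype, each = length(grow)),
      date = rep(dev$date[grow], G),
      ds = rep(ds_g, G),
      agb = as.numeric(agb_track),
      lai = as.numeric(lai_track)
    )
  }
  out
}

#' Simulate rice genotypes over a weather series
#'
#' Runs the daily simulator for every genotype row over every calendar year
#' of the weather series: phenology, radiation-driven growth with
#' temperature, CO2, light-saturation and blast limitations, spikelet
#' sterility, grain quality, and per-hectare value. All genotypes share the
#' weather and model constants, so the whole genotype table is advanced
#' through each day at once; the function is deterministic in its inputs.
#'
#' @param params Genotype tibble with columns `rue`, `k`, `sla_ini`,
#'   `sla_till`, `blast_res`, `t_chalk`, `t_headrice`, `t_coldster`,
#'   `t_heatster` (one row per genotype; an optional `genotype` id column is
#'   preserved).
#' @param weather Daily weather tibble spanning one or more whole years
#'   (columns `date`, `tmin`, `tmax`, `rad`, `rain`, `rh`, `wind`).
#' @param constants A [model_constants()] list.
#' @param co2 Atmospheric CO2, ppm; defaults to the series' `co2` attribute
#'   (set by [generate_weather()]/[apply_scenario()]) or the reference value.
#' @param daily If `TRUE`, attach the daily canopy state (tibble `genotype`,
#'   `date`, `ds`, `agb`, `lai`) as attribute `"daily"` of each year's rows;
#'   intended for small genotype tables (diagnostics, estimator closure
#'   checks).
#' @return A tibble with one row per genotype x year: `genotype`, `year`,
#'   `yield` and `agb` (t/ha), `sterility`, `chalkiness`, `head_rice`
#'   fractions, `value` (euro/ha), `flowering` and `maturity` dates, and a
#'   `complete` flag (seasons too cold to mature are flagged, not errors).
#' @examples
#' w <- generate_weather(site_climate(), years = 2, seed = 1)
#' simulate_crop(mean_genotype(germplasm_distributions()), w)
#' @export
simulate_crop <- function(params, weather, constants = model_constants(),
                          co2 = NULL, daily = FALSE) {
  .check_weather(weather)
  params <- tibble::as_tibble(params)
  if (!"genotype" %in% names(params)) {
    params$genotype <- seq_len(nrow(params))
  }
  .check_params(params)
  if (is.null(co2)) {
    co2 <- attr(weather, "co2") %||% constants$co2_ref
  }
  years <- as.integer(strftime(weather$date, "%Y"))
  res <- purrr::map(split(weather, years), function(wy) {
    .simulate_year(params, wy, constants, co2, daily = daily)
  })
  out <- dplyr::bind_rows(res)
  if (daily) {
    attr(out, "daily") <- dplyr::bind_rows(purrr::map(res, attr, "daily"))
  }
  out
}
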