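#' Cardinal temperatures for photosynthesis
#'
#' Minimum, optimum and maximum temperatures of the beta-type temperature
#' response used both when estimating radiation use efficiency from field data
#' and inside the growth simulator. Defaults are the rice values 12, 28 and
#' 38 degC.
#'
#' @param t_min,t_opt,t_max Cardinal temperatures in degC, `t_min < t_opt < t_max`.
#' @return A named list.
#' @export
cardinal_temperatures <- function(t_min = 12, t_opt = 28, t_max = 38) {
  if (!(t_min < t_opt && t_opt < t_max)) {
    rlang::abort("cardinal temperatures must satisfy t_min < t_opt < t_max.")
  }
  list(t_min = t_min, t_opt = t_opt, t_max = t_max)
}

#' Beta-type temperature response
#'
#' Daily temperature limitation factor in \[0, 1\]:
#' `f(T) = [((t_max - T)/(t_max - t_opt)) * ((T - t_min)/(t_opt - t_min))^q]^c`
#' with `q = (t_opt - t_min)/(t_max - t_opt)`, clipped to 0 outside
#' `[t_min, t_max]`. `f(t_opt) = 1`.
#'
#' @param t Vector of daily mean air temperatures, degC.
#' @param cardinals A [cardinal_temperatures()] list.
#' @param shape Curve exponent `c` (default 1, the simplest member of the
#'   family).
#' @return Numeric vector of factors in \[0, 1\].
#' @export
temperature_response <- function(t, cardinals = cardinal_temperatures(),
                                 shape = 1) {
  tn <- cardinals$t_min
  to <- cardinals$t_opt
  tx <- cardinals$t_max
  q <- (to - tn) / (tx - to)
  f <- ((tx - t) / (tx - to)) * ((t - tn) / (to - tn))^q
  f[t <= tn | t >= tx] <- 0
  pmin(pmax(f, 0), 1)^shape
}

#' Mean thermal limitation over a period
#'
#' Arithmetic mean of the daily beta-type response over a series of daily
#' mean temperatures; the `Tlim` term of the field RUE estimator.
#'
#' @param t_mean Non-empty numeric vector of daily mean air temperatures, degC.
#' @inheritParams temperature_response
#' @return A single number in \[0, 1\]; 1 iff every day sits at `t_opt`.
#' @export
thermal_limitation <- function(t_mean, cardinals = cardinal_temperatures(),
                               shape = 1) {
  if (length(t_mean) == 0L || any(!is.finite(t_mean))) {
    rlang::abort("`t_mean` must be a non-empty finite series.")
  }
  mean(temperature_response(t_mean, cardinals, shape))
}

#' Estimate radiation use efficiency from canopy measurements
#'
#' RUE (g biomass per MJ intercepted PAR) over the interval between two
#' phenological stages (canonically panicle initiation, BBCH 30, and late
#' heading, BBCH 58):
#' `RUE = dAGB / (0.5 * rad_sum * (1 - exp(-k * LAI_mean))) / tlim`
#' where `dAGB` is the aboveground-biomass increment converted from t/ha to
#' g/m2 (x100), 0.5 converts global radiation to PAR, and `LAI_mean` is the
#' mean leaf area index over the interval (arithmetic mean of the two stage
#' measurements by default, logarithmic mean optionally).
#'
#' @param agb_start,agb_end Aboveground biomass at the two stages, t/ha.
#' @param lai_start,lai_end Leaf area index at the two stages, m2/m2.
#' @param rad_sum Cumulated global solar radiation over the interval, MJ/m2.
#' @param k Canopy light extinction coefficient (> 0).
#' @param tlim Mean thermal limitation in (0, 1], from [thermal_limitation()].
#' @param lai_mean `"arithmetic"` (default) or `"log"` mean of the two LAI
#'   measurements.
#' @return RUE in g/MJ (vectorised over its arguments).
#' @examples
#' estimate_rue(2, 8, 3, 5, rad_sum = 450, k = 0.5, tlim = 0.9)
#' @export
estimate_rue <- function(agb_start, agb_end, lai_start, lai_end,
                         rad_sum, k, tlim,
                         lai_mean = c("arithmetic", "log")) {
  lai_mean <- match.arg(lai_mean)
  if (any(rad_sum <= 0)) rlang::abort("`rad_sum` must be positive.")
  if (any(k <= 0)) rlang::abort("`k` must be positive.")
  if (any(tlim <= 0 | tlim > 1)) {
    rlang::abort("`tlim` must lie in (0, 1]; 0 makes RUE undefined.")
  }
  if (any(agb_end < agb_start) || any(agb_start < 0)) {
    rlang::abort("need agb_end >= agb_start >= 0.")
  }
  if (any(lai_start <= 0) || any(lai_end <= 0)) {
    rlang::abort("LAI values must be positive.")
  }
  lai <- if (lai_mean == "arithmetic") {
    (lai_start + lai_end) / 2
  } else {
    ifelse(lai_start == lai_end, lai_start,
      (lai_end - lai_start) / (log(lai_end) - log(lai_start))
    )
  }
  fint <- 1 - exp(-k * lai)
  if (any(fint <= 0)) rlang::abort("zero light interception; RUE undefined.")
  dagb_g_m2 <- (agb_end - agb_start) * 100
  dagb_g_m2 / (0.5 * rad_sum * fint) / tlim
}

#' Ellipsoidal leaf-angle shape parameter from mean leaf inclination
#'
#' Inverts the Campbell (1990) relation between the ellipsoidal shape
#' parameter `x` and the mean leaf inclination angle
#' `a_rad = 9.65 * (3 + x)^(-1.65)`:
#' `x = (a_rad / 9.65)^(-1/1.65) - 3`.
#' Larger mean angles (more erect canopies) give smaller `x`.
#'
#' @param angles_deg Leaf inclination angles in degrees from horizontal,
#'   all in \[0, 90\] (e.g. every leaf angle of a plant measured from insertion
#'   to tip); the sample mean is used.
#' @return The shape parameter `x` (> 0).
#' @examples
#' campbell_x_from_mean_angle(57) # near-spherical canopy
#' @export
campbell_x_from_mean_angle <- function(angles_deg) {
  if (length(angles_deg) == 0L || any(!is.finite(angles_deg))) {
    rlang::abort("`angles_deg` must be non-empty and finite.")
  }
  if (any(angles_deg < 0 | angles_deg > 90)) {
    rlang::abort("leaf angles must lie in [0, 90] degrees.")
  }
  a_deg <- mean(angles_deg)
  if (a_deg <= 0 || a_deg >= 90) {
    rlang::abort("mean leaf angle of 0 or 90 degrees is outside the invertible range.")
  }
  a_rad <- a_deg * pi / 180
  x <- (a_rad / 9.65)^(-1 / 1.65) - 3
  if (x <= 0) {
    rlang::abort("mean angle too steep for the ellipsoidal inversion (x <= 0).")
  }
  x
}

#' Mean leaf inclination implied by an ellipsoidal shape parameter
#'
#' Forward Campbell (1990) relation, the inverse of
#' [campbell_x_from_mean_angle()].
#'
#' @param x Ellipsoidal shape parameter (> 0).
#' @return Mean leaf inclination in degrees.
#' @export
campbell_mean_angle <- function(x) {
  if (any(x <= 0)) rlang::abort("`x` must be positive.")
  9.65 * (3 + x)^(-1.65) * 180 / pi
}

#' Canopy extinction coefficient from the ellipsoidal distribution
#'
#' Campbell's extinction coefficient for direct beam radiation at solar
#' zenith angle `theta`:
#' `k = sqrt(x^2 + tan(theta)^2) / (x + 1.774 * (x + 1.182)^(-0.733))`.
#' A single representative zenith angle (default 30 degrees) collapses the
#' model to one `k` per variety.
#'
#' @param x Ellipsoidal shape parameter (> 0).
#' @param zenith_deg Solar zenith angle in degrees, `0 <= zenith < 90`.
#' @return Extinction coefficient `k` (vectorised).
#' @examples
#' campbell_k(1, zenith_deg = 0) # spherical canopy, overhead sun: ~0.5
#' @export
campbell_k <- function(x, zenith_deg = 30) {
  if (any(x <= 0)) rlang::abort("`x` must be positive.")
  if (any(zenith_deg < 0 | zenith_deg >= 90)) {
    rlang::abort("`zenith_deg` must lie in [0, 90).")
  }
  theta <- zenith_deg * pi / 180
  sqrt(x^2 + tan(theta)^2) / (x + 1.774 * (x + 1.182)^(-0.733))
}

#' Specific leaf area
#'
#' Leaf area per unit leaf dry mass, from scanning all leaves of sampled
#' plants and drying them to constant weight.
#'
#' @param leaf_area_m2 Total leaf area, m2 (> 0).
#' @param dry_mass_kg Leaf dry mass, kg (> 0).
#' @return SLA in m2/kg (vectorised).
#' @export
specific_leaf_area <- function(leaf_area_m2, dry_mass_kg) {
  if (any(leaf_area_m2 <= 0) || any(dry_mass_kg <= 0)) {
    rlang::abort("leaf area and dry mass must be positive.")
  }
  leaf_area_m2 / dry_mass_kg
}

#' Estimate RUE for a panel of field measurements
#'
#' Data-frame-first wrapper: one row per variety with stage biomass/LAI and
#' stage dates; radiation and temperature are pulled from a daily weather
#' table for each variety's interval.
#'
#' @param measurements Tibble with columns `variety`, `date_bbch30`,
#'   `date_bbch58` (Date), `agb30_t_ha`, `agb58_t_ha`, `lai30`, `lai58`, `k`.
#' @param weather Daily weather tibble with columns `date`, `tmin`, `tmax`,
#'   `rad` (MJ/m2), as produced by [generate_weather()] or
#'   [read_weather_csv()].
#' @inheritParams temperature_response
#' @return The input tibble with added columns `rad_sum`, `tlim`, `rue`.
#' @export
estimate_rue_panel <- function(measurements, weather,
                               cardinals = cardinal_temperatures(),
                               shape = 1) {
  needed <- c(
    "variety", "date_bbch30", "date_bbch58",
    "agb30_t_ha", "agb58_t_ha", "lai30", "lai58", "k"
  )
  missing <- setdiff(needed, names(measurements))
  if (length(missing)) {
    rlang::abort(paste0("measurements lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(measurements$date_bbch58 <= measurements$date_bbch30)) {
    rlang::abort("stage dates must be strictly ordered (BBCH 30 before BBCH 58).")
  }
  measurements |>
    dplyr::rowwise() |>
    dplyr::mutate(
      rad_sum = {
        w <- weather[weather$date >= .data$date_bbch30 &
          weather$date <= .data$date_bbch58, ]
        sum(w$rad)
      },
      tlim = {
        w <- weather[weather$date >= .data$date_bbch30 &
          weather$date <= .data$date_bbch58, ]
        thermal_limitation((w$tmin + w$tmax) / 2, cardinals, shape)
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      rue = estimate_rue(
        .data$agb30_t_ha, .data$agb58_t_ha, .data$lai30, .data$lai58,
        .data$rad_sum, .data$k, .data$tlim
      )
    )
}
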