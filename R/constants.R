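#' Model constants of the daily rice simulator
#'
#' Fixed (non-genotypic) constants of the WARM-style daily simulator:
#' phenology thermal-time requirements, biomass partitioning vs. development
#' stage, CO2 and light-saturation response, blast-epidemic coefficients,
#' sterility and grain-quality response rates, and the price/quality-discount
#' schedule used to turn a harvest into a per-hectare value. All values are
#' package defaults calibrated so that a genotype at the germplasm
#' distribution means yields in a realistic 6-12 t/ha band under baseline
#' Po-valley weather; every entry can be overridden by name.
#'
#' Development stage (DS) runs 0 at emergence, 1 at flowering, 2 at
#' physiological maturity; stage anchors (tillering, panicle initiation,
#' heading) are expressed as DS values. Partitioning tables are piecewise
#' linear in DS. Blast resistance classes are 1 (susceptible) to 3 (most
#' resistant).
#'
#' @param ... Named overrides of any default, e.g.
#'   `model_constants(base_price = 320)`.
#' @return A named list of class `model_constants`.
#' @export
model_constants <- function(...) {
  defaults <- list(
    # phenology (thermal time above t_base_dev, degC day)
    t_base_dev = 12,
    gdd_emergence = 70, # sowing -> emergence
    gdd_flowering = 700, # emergence -> flowering (DS 1)
    gdd_maturity = 420, # flowering -> maturity (DS 2)
    ds_tillering = 0.25,
    ds_panicle_init = 0.6,
    ds_heading = 0.95,
    sowing_doy = 135,
    # photosynthesis
    cardinals = cardinal_temperatures(12, 28, 38),
    beta_shape = 1,
    co2_ref = 360, # ppm
    co2_slope = 8e-4, # fractional RUE gain per ppm above co2_ref
    sat_ipar = 10, # cap on daily intercepted PAR, MJ/m2/day
    agb_ini = 0.05, # aboveground biomass at emergence, t/ha
    # partitioning: fraction of daily AGB to leaves / panicles vs DS
    partition_leaf = list(
      ds = c(0, 0.5, 1, 1.2, 2),
      frac = c(0.55, 0.48, 0.12, 0, 0)
    ),
    partition_panicle = list(
      ds = c(0, 0.62, 1.05, 2),
      frac = c(0, 0, 0.85, 0.85)
    ),
    senescence_rate = 0.015, # relative LAI loss per day per DS unit above 1
    # blast epidemic (generic airborne fungal pathogen)
    blast_cardinals = cardinal_temperatures(10, 22, 32),
    blast_rh_threshold = 85, # % RH for a leaf-wetness-conducive day
    blast_rate = c(0.012, 0.006, 0.002), # daily infection rate, class 1..3
    blast_max_impact = 0.5, # max fractional RUE reduction
    # spikelet sterility
    cold_window_ds = c(0.75, 1.0), # booting (pre-flowering cold)
    heat_window_ds = c(0.96, 1.06), # flowering (heat)
    cold_rate = 0.08, # per degC day below t_coldster (on Tmin)
    heat_rate = 0.08, # per degC day above t_heatster (on Tmax)
    # grain quality
    chalk_rate = 0.04, # per degC day of Tmean above t_chalk after heading
    headrice_rate = 0.02, # per degC day of Tmin above t_headrice
    wind_threshold = 5, # m/s; excess contributes to milling breakage
    wind_rate = 0.004,
    rain_threshold = 25, # mm/day
    rain_rate = 0.002,
    # economics
    base_price = 300, # euro per t of paddy
    chalk_discount = 0.6, # price multiplier drops by this x chalkiness
    headrice_discount = 0.5 # ... and by this x (1 - head rice fraction)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    rlang::abort(paste0("unknown constant(s): ", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, overrides)
  stopifnot(
    out$gdd_emergence > 0, out$gdd_flowering > 0, out$gdd_maturity > 0,
    all(out$partition_leaf$frac >= 0 & out$partition_leaf$frac <= 1),
    all(out$partition_panicle$frac >= 0 & out$partition_panicle$frac <= 1),
    {
      grid <- seq(0, 2, by = 0.05)
      lf <- stats::approx(out$partition_leaf$ds, out$partition_leaf$frac, grid, rule = 2)$y
      pf <- stats::approx(out$partition_panicle$ds, out$partition_panicle$frac, grid, rule = 2)$y
      all(lf + pf <= 1 + 1e-9)
    },
    length(out$blast_rate) == 3L, all(out$blast_rate > 0),
    out$base_price > 0, out$chalk_discount < 1, out$headrice_discount < 1
  )
  structure(out, class = "model_constants")
}

#' Genotype tibble from a distribution set's means
#'
#' The "mean genotype" used as the reference when quantifying ideotype
#' benefits: each continuous parameter at its distribution mean, discrete
#' parameters at the level nearest their mean.
#'
#' @param dset A complete distribution set.
#' @return A one-row genotype tibble with the nine crop-parameter columns
#'   `rue`, `k`, `sla_ini`, `sla_till`, `blast_res`, `t_chalk`, `t_headrice`,
#'   `t_coldster`, `t_heatster`.
#' @export
mean_genotype <- function(dset) {
  dset <- validate_complete_set(dset)
  vals <- purrr::map2_dbl(dset$family, seq_len(nrow(dset)), function(fam, i) {
    if (fam == "normal") {
      dset$mean[i]
    } else {
      lv <- dset$levels[[i]]
      lv[which.min(abs(lv - mean(lv)))]
    }
  })
  out <- tibble::as_tibble(as.list(stats::setNames(vals, unname(.param_cols))))
  out$blast_res <- round(out$blast_res)
  out
}
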