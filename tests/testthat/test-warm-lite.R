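germ_mean <- mean_genotype(germplasm_distributions())

test_that("phenology accumulates thermal time above the base temperature", {
  # at the base temperature nothing develops
  cold <- constant_weather(tmean = 12)
  dev <- develop(cold)
  expect_true(all(is.na(dev$ds)))
  expect_false(attr(dev, "complete"))

  # 13 degC day per day at 25 degC: a 130 degC-day requirement is met on day 10
  warm <- constant_weather(tmean = 25)
  dev <- develop(warm, model_constants(gdd_emergence = 130))
  stages <- attr(dev, "stages")
  expect_equal(as.integer(stages$emergence - stages$sowing) + 1L, 10L)

  # development stage never decreases and is capped at 2
  dev <- develop(constant_weather(tmean = 28))
  ds <- dev$ds[!is.na(dev$ds)]
  expect_true(all(diff(ds) >= 0))
  expect_lte(max(ds), 2)

  # a warmer season matures earlier or on the same day
  w <- fixture_weather(years = 1)
  m_base <- attr(develop(w), "stages")$maturity
  m_warm <- attr(develop(apply_scenario(w, delta_t = 2)), "stages")$maturity
  expect_lte(as.integer(m_warm), as.integer(m_base))
})

test_that("daily growth follows Lambert-Beer interception", {
  # no radiation, no growth
  dark <- constant_weather(tmean = 28, rad = 0)
  sim <- simulate_crop(germ_mean, dark)
  expect_equal(sim$agb, model_constants()$agb_ini)
  expect_equal(sim$yield, 0)

  # closed canopy at the optimum: daily gain approaches rue * 0.5 * rad
  cst <- model_constants(sat_ipar = 1e6)
  big_canopy <- dplyr::mutate(germ_mean, sla_ini = 80, sla_till = 80, k = 1.2)
  sim <- simulate_crop(big_canopy, constant_weather(rad = 10), cst, daily = TRUE)
  track <- attr(sim, "daily")
  gains <- diff(track$agb)
  # late-season (closed canopy, pre-senescence) daily gains in t/ha
  mid <- which(track$ds[-1] > 0.6 & track$ds[-1] < 1)
  expect_equal(
    gains[mid], rep(germ_mean$rue * 0.5 * 10 * 0.01, length(mid)),
    tolerance = 0.01
  )

  # interception ratio when doubling k at equal LAI, read off day-one growth
  two_k <- dplyr::bind_rows(germ_mean, dplyr::mutate(germ_mean, k = 2 * germ_mean$k))
  sim2 <- simulate_crop(two_k, constant_weather(rad = 10), cst, daily = TRUE)
  tr <- attr(sim2, "daily")
  first <- tr[tr$date == min(tr$date), ]
  lai0 <- model_constants()$agb_ini * 0.1 * 0.55 * germ_mean$sla_ini
  gain1 <- first$agb[first$genotype == 1] - cst$agb_ini
  gain2 <- first$agb[first$genotype == 2] - cst$agb_ini
  expect_equal(
    gain2 / gain1,
    (1 - exp(-2 * germ_mean$k * lai0)) / (1 - exp(-germ_mean$k * lai0)),
    tolerance = 1e-9
  )
})

test_that("blast pressure responds to resistance class and wetness", {
  w <- fixture_weather(years = 1, seed = 7)
  dev <- develop(w)
  season <- w[w$date >= dev$date[1], ]

  m1 <- blast_pressure(season, 1)
  m3 <- blast_pressure(season, 3)
  expect_true(all(m3 >= m1))
  expect_true(all(m1 > 0 & m1 <= 1))
  expect_true(all(diff(m1) <= 0)) # severity only accumulates

  # bone-dry season: no infection at all
  dry <- dplyr::mutate(season, rh = 40, rain = 0)
  expect_equal(blast_pressure(dry, 1), rep(1, nrow(dry)))

  # frozen fixture value for the epidemic year (regression guard)
  expect_equal(mean(m1), 0.8600734, tolerance = 1e-6)

  expect_error(blast_pressure(season, 4), "class")
})

test_that("spikelet sterility accumulates bell-weighted threshold exceedances", {
  w <- fixture_weather(years = 1)
  dev <- develop(w)
  season <- w[w$date >= dev$date[1], ]

  # generous thresholds: nothing sterilizes
  expect_equal(spikelet_sterility(season, dev$ds, t_coldster = -20, t_heatster = 60), 0)

  # lowering the heat threshold can only increase sterility
  s_high <- spikelet_sterility(season, dev$ds, 13.5, 34.4)
  s_low <- spikelet_sterility(season, dev$ds, 13.5, 29.4)
  expect_gte(s_low, s_high)

  # single flowering day at bell centre, Tmax 2 degC above threshold:
  # sterility equals the per-degree-day response at 2 degC
  cst <- model_constants()
  mid <- mean(cst$heat_window_ds)
  one <- constant_weather(tmean = 25)[1:3, ]
  one$tmax <- c(25, 36.4, 25)
  ds <- c(0.5, mid, 1.5) # only the middle day is in the heat window
  ster <- spikelet_sterility(one, ds, t_coldster = -20, t_heatster = 34.4, cst)
  expect_equal(ster, 1 - exp(-cst$heat_rate * 2), tolerance = 1e-12)

  # always a fraction
  expect_true(all(
    spikelet_sterility(season, dev$ds, seq(5, 25, 5), seq(25, 45, 5)) >= 0
  ))
  expect_true(all(
    spikelet_sterility(season, dev$ds, seq(5, 25, 5), seq(25, 45, 5)) <= 1
  ))
})

test_that("grain quality responds to post-heading heat, nights, wind and rain", {
  w <- fixture_weather(years = 1)
  dev <- develop(w)
  season <- w[w$date >= dev$date[1], ]

  q <- grain_quality(season, dev$ds, t_chalk = 60, t_headrice = 60)
  expect_equal(q$chalkiness, 0)

  # raising the chalkiness threshold cannot increase chalkiness
  q_lo <- grain_quality(season, dev$ds, 22, 23.9)
  q_hi <- grain_quality(season, dev$ds, 28, 23.9)
  expect_lte(q_hi$chalkiness, q_lo$chalkiness)

  # 10 degree-days above threshold through the saturating response
  cst <- model_constants()
  three <- constant_weather(tmean = 25)[1:3, ]
  three$tmin <- c(20, 20, 20)
  three$tmax <- c(40, 40, 40) # tmean 30 on fill days
  ds <- c(1.2, 1.5, 0.1) # two days in the grain-fill window
  q <- grain_quality(three, ds, t_chalk = 25, t_headrice = 60, cst)
  expect_equal(q$chalkiness, 1 - exp(-cst$chalk_rate * 10), tolerance = 1e-12)

  expect_true(all(q$head_rice >= 0 & q$head_rice <= 1))
})

test_that("crop value prices yield and discounts poor quality", {
  expect_equal(crop_value(0, 0.3, 0.8), 0)
  cst <- model_constants()
  expect_equal(crop_value(8, 0, 1, cst), 8 * cst$base_price)
  expect_lt(crop_value(8, 0.3, 0.9), crop_value(8, 0.1, 0.9))
  expect_gt(crop_value(8, 0.1, 0.95), crop_value(8, 0.1, 0.7))
  expect_error(crop_value(8, 1.2, 0.9), "\\[0, 1\\]")
})

test_that("simulate_crop is deterministic and conserves biomass", {
  w <- fixture_weather(years = 2)
  s1 <- simulate_crop(germ_mean, w)
  s2 <- simulate_crop(germ_mean, w)
  expect_identical(s1, s2)

  # cumulative daily gains equal the final biomass; yield never exceeds it
  sim <- simulate_crop(germ_mean, constant_weather(), daily = TRUE)
  track <- attr(sim, "daily")
  cst <- model_constants()
  expect_equal(
    cst$agb_ini + sum(diff(c(cst$agb_ini, track$agb))), sim$agb,
    tolerance = 1e-9
  )
  expect_true(all(s1$yield <= s1$agb))
  expect_true(all(s1$yield <= s1$agb * max(cst$partition_panicle$frac)))
})

test_that("mean germplasm genotype yields in the calibrated band", {
  w <- generate_weather(site_climate(), years = 20, seed = 11)
  sim <- simulate_crop(germ_mean, w)
  expect_gte(sum(sim$complete), 18)
  expect_gt(mean(sim$yield), 6)
  expect_lt(mean(sim$yield), 12)
  expect_true(all(sim$sterility >= 0 & sim$sterility <= 1))
  expect_true(all(sim$chalkiness >= 0 & sim$chalkiness <= 1))
  expect_true(all(sim$head_rice >= 0 & sim$head_rice <= 1))
  expect_true(all(sim$value >= 0))
})

test_that("output value responds monotonically to traits in a mild year", {
  w <- constant_weather(rad = 18) # optimal temperature, dry, no stress
  variants <- dplyr::bind_rows(
    germ_mean,
    dplyr::mutate(germ_mean, rue = rue * 1.1),
    dplyr::mutate(germ_mean, k = k * 1.2),
    dplyr::mutate(germ_mean, blast_res = 1)
  )
  sim <- simulate_crop(variants, w)
  expect_gt(sim$yield[2], sim$yield[1]) # +10% RUE
  expect_gte(sim$value[3], sim$value[1]) # higher k intercepts more
  expect_lte(sim$value[4], sim$value[1]) # susceptibility cannot help

  # CO2 fertilization: 450 ppm at least as good as 360 ppm
  v450 <- simulate_crop(germ_mean, w, co2 = 450)
  v360 <- simulate_crop(germ_mean, w, co2 = 360)
  expect_gte(v450$value, v360$value)
})

test_that("a season too cold to mature is flagged, not an error", {
  site <- site_climate(t_annual_mean = 6, t_amplitude = 7)
  w <- generate_weather(site, years = 1, seed = 2)
  sim <- simulate_crop(germ_mean, w)
  expect_false(any(sim$complete))
  expect_equal(nrow(sim), 1)
})

test_that("genotype tables are validated", {
  w <- fixture_weather(years = 1)
  bad <- dplyr::mutate(germ_mean, rue = -1)
  expect_error(simulate_crop(bad, w), "positive")
  bad2 <- dplyr::mutate(germ_mean, blast_res = 5)
  expect_error(simulate_crop(bad2, w), "blast_res")
  expect_error(simulate_crop(germ_mean[, -1], w), "lacks")
})
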