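# Shared fixtures, all generated in code.

# constant stress-free weather: one full year at the photosynthetic optimum,
# dry and still, for closure/monotonicity checks
constant_weather <- function(tmean = 28, rad = 20, rh = 50, rain = 0,
                             wind = 1, year = 2001) {
  d <- seq(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-12-31", year)),
    by = "day"
  )
  out <- tibble::tibble(
    date = d, tmin = tmean, tmax = tmean, rad = rad, rain = rain,
    rh = rh, wind = wind
  )
  attr(out, "co2") <- 360
  out
}

# small seeded baseline weather reused across tests
fixture_weather <- function(years = 2, seed = 5) {
  generate_weather(site_climate(), years = years, seed = seed)
}

# evaluate a radial design over a weather series: mean output per design row
evaluate_design <- function(design, weather, constants = model_constants(),
                            metric = "value") {
  sim <- simulate_crop(
    dplyr::mutate(tibble::as_tibble(design), genotype = dplyr::row_number()),
    weather, constants
  )
  as.numeric(
    tapply(sim[[metric]], sim$genotype, mean)[as.character(seq_len(nrow(design)))]
  )
}

# design whose outputs depend only on RUE and k, standardized to N(0,1):
# f = 2 * z_RUE + z_k has analytic total-order indices 0.8 and 0.2
additive_test_outputs <- function(design, dset) {
  z1 <- (design$rue - dset$mean[dset$name == "RUE"]) / dset$sd[dset$name == "RUE"]
  z2 <- (design$k - dset$mean[dset$name == "k"]) / dset$sd[dset$name == "k"]
  2 * z1 + z2
}

# independent brute-force Savage-score concordance, kept deliberately naive
tdcc_oracle <- function(r1, r2) {
  n <- length(r1)
  savage <- function(rank) {
    out <- 0
    for (j in rank:n) out <- out + 1 / j
    out
  }
  items <- sort(r1)
  s1 <- vapply(match(items, r1), savage, numeric(1))
  s2 <- vapply(match(items, r2), savage, numeric(1))
  denom <- n - sum(1 / seq_len(n))
  (sum(s1 * s2) - n) / denom
}
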