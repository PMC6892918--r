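test_that("fit_normal returns sample moments and rejects degenerate input", {
  # jitter pattern around 28.70: mean and sd by hand
  fit <- fit_normal(28.70 + c(-0.1, 0, 0.1), name = "SLAtill")
  expect_equal(fit$mean, 28.70)
  expect_equal(fit$sd, 0.1)
  expect_identical(fit$family, "normal")

  expect_error(fit_normal(c(1, 2)), "at least 3")
  expect_error(fit_normal(rep(5, 10)), "zero variance")

  # seeded draws recover the generating mean within 3 standard errors
  withr::with_seed(421, {
    x <- rnorm(43, 2.72, 0.23)
  })
  fit <- fit_normal(x)
  expect_lt(abs(fit$mean - 2.72), 3 * 0.23 / sqrt(43))

  # large-sample recovery within 1 percent of the generating parameters
  withr::with_seed(99, {
    big <- rnorm(10000, 2.72, 0.23)
  })
  fit <- fit_normal(big)
  expect_lt(abs(fit$mean - 2.72) / 2.72, 0.01)
  expect_lt(abs(fit$sd - 0.23) / 0.23, 0.01)
})

test_that("shapiro_wilk behaves like a calibrated normality test", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")

  # perfectly symmetric tiny sample: W close to 1
  expect_gt(shapiro_wilk(c(-2, -1, 0, 1, 2))$statistic, 0.9)

  # nominal type-I error: normal samples accepted in >= 90% of seeds,
  # and W is lower for uniform samples than matched normal ones on average
  res <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      nrm <- rnorm(43, 2.72, 0.23)
      unif <- runif(43, 0, 1)
    })
    c(
      p_norm = shapiro_wilk(nrm)$p_value,
      w_norm = shapiro_wilk(nrm)$statistic,
      w_unif = shapiro_wilk(unif)$statistic
    )
  }, numeric(3))
  expect_gte(mean(res["p_norm", ] > 0.05), 0.90)
  expect_lt(mean(res["w_unif", ]), mean(res["w_norm", ]))
})

test_that("ks_compare covers samples, fitted normals, and their mixtures", {
  x <- rnorm(50)
  expect_equal(ks_compare(x, x)$D, 0)

  d <- trait_distribution("k", "normal", mean = 0.58, sd = 0.10)
  expect_equal(ks_compare(d, d)$D, 0)

  # the two published k distributions are far apart ...
  lit_k <- trait_distribution("k", "normal", mean = 0.47, sd = 0.04)
  expect_gt(ks_compare(d, lit_k)$D, 0.4)
  # ... while the two SLAtill distributions overlap almost entirely
  a <- trait_distribution("SLAtill", "normal", mean = 28.70, sd = 3.18)
  b <- trait_distribution("SLAtill", "normal", mean = 28.68, sd = 3.89)
  expect_lt(ks_compare(a, b)$D, 0.1)

  # closed-form D cross-checked against a dense grid computed independently
  grid <- seq(-1, 2, length.out = 200001)
  d_grid <- max(abs(pnorm(grid, 0.58, 0.10) - pnorm(grid, 0.47, 0.04)))
  expect_equal(ks_compare(d, lit_k)$D, d_grid, tolerance = 1e-6)

  # sample vs theoretical normal uses the asymptotic two-sided test
  withr::with_seed(7, smp <- rnorm(100, 0.58, 0.10))
  res <- ks_compare(smp, d)
  expect_true(res$D >= 0 && res$D <= 1)
  expect_true(res$p_value >= 0 && res$p_value <= 1)

  disc <- trait_distribution("BlastRes", "discrete", levels = 1:3)
  expect_error(ks_compare(disc, d), "normal")
})

test_that("packaged distribution sets load exactly as published", {
  germ <- germplasm_distributions()
  lit <- literature_distributions()
  for (set in list(germ, lit)) {
    expect_setequal(set$name, trait_parameter_names())
    expect_equal(nrow(set), 9)
  }
  gv <- function(set, p, f) set[[f]][set$name == p]
  expect_equal(gv(germ, "RUE", "mean"), 2.72)
  expect_equal(gv(germ, "RUE", "sd"), 0.23)
  expect_equal(gv(germ, "k", "mean"), 0.58)
  expect_equal(gv(germ, "SLAini", "mean"), 35)
  expect_equal(gv(germ, "SLAtill", "sd"), 3.18)
  expect_equal(gv(lit, "RUE", "mean"), 2.68)
  expect_equal(gv(lit, "RUE", "sd"), 0.09)
  expect_equal(gv(lit, "k", "mean"), 0.47)
  expect_equal(gv(lit, "k", "sd"), 0.04)
  expect_equal(gv(lit, "SLAini", "sd"), 5.9)
  expect_identical(gv(germ, "BlastRes", "family"), "discrete")
  expect_equal(germ$levels[germ$name == "BlastRes"][[1]], c(1, 2, 3))
  # shared stress/quality parameters are identical across the two sets
  shared <- c("T-Chalkiness", "T-HeadRice", "T-ColdSter", "T-HeatSter")
  expect_equal(
    as.data.frame(germ)[germ$name %in% shared, c("mean", "sd")],
    as.data.frame(lit)[lit$name %in% shared, c("mean", "sd")]
  )
})

test_that("distribution sets round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  germ <- germplasm_distributions()
  write_distribution_set(germ, path)
  back <- read_distribution_set(path, label = "germplasm")
  expect_equal(
    tibble::as_tibble(back)[c("name", "family", "mean", "sd", "units")],
    tibble::as_tibble(germ)[c("name", "family", "mean", "sd", "units")]
  )
  expect_equal(back$levels, germ$levels)
})

test_that("trait_distribution validates its invariants", {
  expect_error(trait_distribution("RUE", "normal", mean = 2.7, sd = 0), "range")
  expect_error(trait_distribution("BlastRes", "discrete", levels = c(3, 2, 1)), "increasing")
  expect_error(
    distribution_set(
      trait_distribution("RUE", "normal", 2.7, 0.2),
      trait_distribution("RUE", "normal", 2.6, 0.1)
    ),
    "unique"
  )
})

test_that("pearson_correlations is symmetric with exact unit diagonals", {
  withr::with_seed(11, {
    panel <- tibble::tibble(
      variety = sprintf("V%02d", 1:43),
      RUE = rnorm(43, 2.72, 0.23),
      k = rnorm(43, 0.58, 0.10)
    )
  })
  panel$k2 <- panel$k
  panel$neg <- -panel$RUE
  res <- pearson_correlations(panel)
  expect_equal(res$r[res$trait_a == "k" & res$trait_b == "k2"], 1)
  expect_equal(res$r[res$trait_a == "RUE" & res$trait_b == "neg"], -1)
  expect_equal(res$r[res$trait_a == "RUE" & res$trait_b == "RUE"], 1)
  # symmetry
  wide <- tidyr::pivot_wider(res[c("trait_a", "trait_b", "r")],
    names_from = "trait_b", values_from = "r"
  )
  m <- unname(as.matrix(wide[-1]))
  expect_equal(m, t(m))

  panel$flat <- 1
  expect_error(pearson_correlations(panel), "constant")
})

test_that("independent traits show no spurious correlation at panel size", {
  hits <- vapply(1:200, function(s) {
    withr::with_seed(1000 + s, {
      a <- rnorm(43)
      b <- rnorm(43)
    })
    abs(cor(a, b)) < 0.45
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fit_trait_distributions fits every numeric column of a panel", {
  panel <- generate_panel(germplasm_distributions(), 50, seed = 3)
  fits <- fit_trait_distributions(panel)
  expect_setequal(fits$name, c("RUE", "k", "SLAini", "SLAtill"))
  expect_true(all(fits$family == "normal"))
})

test_that("trait panels round-trip through CSV", {
  panel <- generate_panel(germplasm_distributions(), 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_panel(panel, path)
  expect_equal(as.data.frame(read_trait_panel(path)), as.data.frame(panel))
})
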