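germ <- germplasm_distributions()

test_that("ideotype score reproduces its zero cases and hand example", {
  # every trait at its mean: feasibility term is zero whatever the value
  expect_equal(ideotype_score(c(1, 2), m = c(1, 2), s = c(0.5, 0.5), y = 10, y_max = 100), 0)
  # best performer: performance term is zero whatever the deviations
  expect_equal(ideotype_score(c(3, 9), m = c(1, 2), s = c(0.5, 0.5), y = 100, y_max = 100), 0)
  # hand-computed case: deviations {10%, 0%}, s {0.25, 1}, y/y_max 0.8
  expect_equal(
    ideotype_score(c(1.1, 2), m = c(1, 2), s = c(0.25, 1), y = 80, y_max = 100),
    2.0
  )
  expect_error(ideotype_score(c(1, 2), c(1, 2), c(0.5, 0.5), y = 101, y_max = 100), "y_max")
  expect_error(ideotype_score(c(1, 2), c(0, 2), c(0.5, 0.5), y = 1, y_max = 100), "zero")
})

test_that("ideotype score weights deviations by inverse root sensitivity", {
  # dividing s_i by 4 doubles parameter i's contribution
  base <- ideotype_score(c(1.2, 2), m = c(1, 2), s = c(0.16, 1), y = 50, y_max = 100)
  quartered <- ideotype_score(c(1.2, 2), m = c(1, 2), s = c(0.04, 1), y = 50, y_max = 100)
  expect_equal(quartered, 2 * base)

  # non-negativity over random inputs
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(2:9, 1)
      m <- runif(n, 0.5, 40)
      x <- m * runif(n, 0.7, 1.3)
      s <- runif(n, 0, 1)
      y <- runif(1, 0, 90)
      expect_gte(ideotype_score(x, m, s, y, y_max = 100), 0)
    }
  })
})

test_that("profile derivation averages the top-ranked fraction", {
  w <- fixture_weather(years = 2)
  design <- sample_radial(germ, 20, seed = 9) # 200 combinations
  outs <- evaluate_design(design, w)
  sr <- total_order(design, outs)
  prof <- derive_profile(design, outs, sr, germ, fraction = 0.01)
  expect_equal(attr(prof, "n_averaged"), 2L) # ceiling(0.01 * 200)
  expect_equal(prof$parameter, trait_parameter_names())
  # stored deviations are consistent with values and means
  expect_equal(prof$deviation_pct, 100 * (prof$value - prof$mean) / prof$mean)
  # discrete blast resistance is reported on its own levels
  expect_true(prof$value[prof$parameter == "BlastRes"] %in% 1:3)

  # degenerate design: every combination identical -> profile equals it
  flat <- design
  for (col in setdiff(names(flat), c("base_index", "perturbed"))) {
    flat[[col]] <- rep(flat[[col]][1], nrow(flat))
  }
  prof_flat <- derive_profile(flat, rep(1, nrow(flat)), sr, germ,
    fraction = 0.05
  )
  expect_equal(
    prof_flat$value[prof_flat$parameter == "RUE"], flat$rue[1]
  )
  expect_equal(
    prof_flat$deviation_pct[prof_flat$parameter == "k"],
    100 * (flat$k[1] - 0.58) / 0.58
  )

  expect_error(derive_profile(design[0, ], numeric(0), sr, germ), "empty")
  expect_error(derive_profile(design, outs, sr, germ, fraction = 0), "fraction")
})

test_that("fixture-study profile matches its frozen golden values", {
  w <- fixture_weather(years = 2, seed = 5)
  design <- sample_radial(germ, 128, seed = 9)
  outs <- evaluate_design(design, w)
  sr <- total_order(design, outs)
  prof <- derive_profile(design, outs, sr, germ)
  golden <- c(
    RUE = 15.43425338, k = -0.99254427, SLAini = -1.36329932,
    SLAtill = 0.36326047, BlastRes = 50, `T-Chalkiness` = 2.00857029,
    `T-HeadRice` = -2.45199277, `T-ColdSter` = -0.08830956,
    `T-HeatSter` = 0.33754834
  )
  expect_equal(
    stats::setNames(prof$deviation_pct, prof$parameter), golden,
    tolerance = 1e-6
  )
})

test_that("yield benefit is zero for the mean genotype and positive for better traits", {
  w <- fixture_weather(years = 3)
  # a profile equal to the distribution means
  mg <- mean_genotype(germ)
  prof_mean <- tibble::tibble(
    parameter = trait_parameter_names(),
    value = as.numeric(mg[1, ]),
    mean = as.numeric(mg[1, ]),
    deviation_pct = 0
  )
  class(prof_mean) <- c("ideotype_profile", class(prof_mean))
  attr(prof_mean, "n_averaged") <- 1L
  b0 <- yield_benefit(prof_mean, germ, w)
  expect_equal(b0$mean_benefit_pct, 0)
  expect_equal(b0$sd_benefit_pct, 0)
  expect_equal(b0$years, 3)

  # +10% RUE only: strictly positive benefit in every year
  prof_rue <- prof_mean
  prof_rue$value[prof_rue$parameter == "RUE"] <- mg$rue * 1.1
  prof_rue$deviation_pct[prof_rue$parameter == "RUE"] <- 10
  b1 <- yield_benefit(prof_rue, germ, w)
  expect_gt(b1$mean_benefit_pct, 0)
  expect_true(all(attr(b1, "by_year")$benefit_pct > 0))

  expect_error(yield_benefit(prof_mean, germ, w[1:300, ]), "2 years")
})

test_that("fixture-study benefit matches its frozen golden values", {
  w <- fixture_weather(years = 2, seed = 5)
  design <- sample_radial(germ, 128, seed = 9)
  outs <- evaluate_design(design, w)
  sr <- total_order(design, outs)
  prof <- derive_profile(design, outs, sr, germ)
  b <- yield_benefit(prof, germ, w)
  expect_equal(b$mean_benefit_pct, 23.99451077, tolerance = 1e-6)
  expect_equal(b$sd_benefit_pct, 3.73751380, tolerance = 1e-6)
})

test_that("profiles are stable against doubling the design size", {
  w <- fixture_weather(years = 5, seed = 5)
  prof_at <- function(bn) {
    design <- sample_radial(germ, bn, seed = 9)
    outs <- evaluate_design(design, w)
    derive_profile(design, outs, total_order(design, outs), germ)
  }
  p512 <- prof_at(512)
  p1024 <- prof_at(1024)
  expect_lt(max(abs(p512$deviation_pct - p1024$deviation_pct)), 3)
})

test_that("ideotype profiles expose tidy, glance and plots", {
  w <- fixture_weather(years = 2)
  design <- sample_radial(germ, 32, seed = 4)
  outs <- evaluate_design(design, w)
  prof <- derive_profile(design, outs, total_order(design, outs), germ,
    scenario = "baseline"
  )
  expect_equal(glance(prof)$scenario, "baseline")
  expect_s3_class(tidy(prof), "tbl_df")
  expect_s3_class(autoplot(prof), "ggplot")
  gt <- profile_genotype(prof)
  expect_equal(gt$rue, prof$value[prof$parameter == "RUE"])
})
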