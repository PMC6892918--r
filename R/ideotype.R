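# Ideotype scoring and profile derivation: rank sampled trait combinations
# by a feasibility-weighted performance score, average the top fraction into
# an ideotype profile, and quantify its benefit against the mean genotype.

#' Ideotype score of candidate trait combinations
#'
#' For a combination with parameter values `x_i`, distribution means `m_i`,
#' total-order indices `s_i`, and value `y` normalized to the maximum value
#' `y_max` over all candidates:
#' `score = [ sum_i ( (|x_i - m_i| / m_i * 100) / sqrt(s_i) ) / n ] * (1 - y / y_max)`.
#' Lower is better: the score reaches 0 when every trait sits at its
#' distribution mean (nothing to breed for) or when the combination attains
#' the maximum value. Deviations of parameters with small sensitivity
#' indices are penalized more (`1/sqrt(s)`): changing an uninfluential trait
#' costs feasibility without buying performance.
#'
#' @param x Genotype values: a numeric vector (one combination) or a matrix /
#'   data frame with one column per parameter and one row per combination.
#' @param m Distribution means, same parameter order as `x` columns; all
#'   non-zero.
#' @param s Total-order indices; values below `s_floor` are floored so that
#'   null parameters do not blow up the weighting.
#' @param y Value of each combination (euro/ha), `y <= y_max`.
#' @param y_max Maximum value across all candidates under evaluation.
#' @param s_floor Floor applied to `s` (default 1e-4).
#' @return Numeric vector of non-negative scores, one per combination.
#' @examples
#' ideotype_score(c(1.1, 2), m = c(1, 2), s = c(0.25, 1), y = 80, y_max = 100)
#' @export
ideotype_score <- function(x, m, s, y, y_max, s_floor = 1e-4) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (length(m) != n || length(s) != n) {
    rlang::abort("`m` and `s` must have one entry per parameter column of `x`.")
  }
  if (any(m == 0)) rlang::abort("zero distribution mean: relative deviation undefined.")
  if (any(y > y_max + 1e-12)) rlang::abort("`y` must not exceed `y_max`.")
  s <- pmax(s, s_floor)
  dev_pct <- abs(sweep(x, 2, m, "-")) %*% diag(100 / abs(m), n, n)
  weighted <- dev_pct %*% (1 / sqrt(s)) / n
  as.numeric(weighted) * (1 - y / y_max)
}

#' Derive an ideotype profile from a scored design
#'
#' Scores every sampled combination with [ideotype_score()], ranks them
#' ascending (lower score = better), and averages the parameter values of
#' the top `fraction` of combinations (ceiling, minimum 1) — averaging
#' rather than taking the single best smooths over local minima of the
#' parameter space. The discrete blast-resistance class is averaged and
#' rounded to the nearest level. Deviations are expressed against the
#' distribution means.
#'
#' @param design A [sample_radial()] design.
#' @param outputs Value per design row (euro/ha, averaged over simulated
#'   years), aligned with `design`.
#' @param st A `sensitivity_result` from [total_order()] on the same design.
#' @param dset The distribution set the design was sampled from.
#' @param fraction Top fraction to average, in (0, 1\]; default 0.01.
#' @param scenario Label stored with the profile.
#' @return An `ideotype_profile` object: tibble with columns `parameter`,
#'   `value`, `mean`, `deviation_pct`, plus attributes `n_averaged` and
#'   `scenario`.
#' @export
derive_profile <- function(design, outputs, st, dset, fraction = 0.01,
                           scenario = NA_character_) {
  if (nrow(design) == 0L) rlang::abort("empty design.")
  if (fraction <= 0 || fraction > 1) rlang::abort("`fraction` must lie in (0, 1].")
  dset <- validate_complete_set(dset)
  params <- dset$name
  cols <- unname(.param_cols[params])
  means <- mean_genotype(dset)
  m <- as.numeric(means[1, cols])
  s <- st$st$st[match(params, st$st$parameter)]
  scores <- ideotype_score(
    as.matrix(design[cols]), m, s,
    y = outputs, y_max = max(outputs)
  )
  n_top <- max(1L, ceiling(fraction * nrow(design)))
  top <- order(scores)[seq_len(n_top)]
  vals <- colMeans(as.matrix(design[top, cols]))
  vals["blast_res"] <- round(vals["blast_res"])
  out <- tibble::tibble(
    parameter = params,
    value = as.numeric(vals),
    mean = m,
    deviation_pct = 100 * (as.numeric(vals) - m) / m
  )
  attr(out, "n_averaged") <- n_top
  attr(out, "scenario") <- scenario
  class(out) <- c("ideotype_profile", class(out))
  out
}

#' Genotype tibble of an ideotype profile
#'
#' @param profile An [derive_profile()] result.
#' @return A one-row genotype tibble usable with [simulate_crop()].
#' @export
profile_genotype <- function(profile) {
  stopifnot(inherits(profile, "ideotype_profile"))
  vals <- stats::setNames(profile$value, unname(.param_cols[profile$parameter]))
  out <- tibble::as_tibble(as.list(vals))
  out$blast_res <- round(out$blast_res)
  out
}

#' Benefit of an ideotype over the mean genotype
#'
#' Simulates the ideotype and the genotype defined by the distribution means
#' year by year over the same weather, and summarizes the per-year relative
#' benefit `100 * (x_profile - x_mean) / x_mean` (on per-hectare value by
#' default, or raw yield) as a mean and a standard deviation across years.
#' Years in which the mean genotype produces nothing are excluded with a
#' warning.
#'
#' @param profile An `ideotype_profile`.
#' @param dset The distribution set defining the mean genotype.
#' @param weather Weather series covering at least 2 years.
#' @param constants A [model_constants()] list.
#' @param metric `"value"` (euro/ha, default) or `"yield"` (t/ha).
#' @param co2 Passed to [simulate_crop()].
#' @return A one-row tibble `mean_benefit_pct`, `sd_benefit_pct`, `years`,
#'   with the per-year benefits in attribute `by_year`.
#' @export
yield_benefit <- function(profile, dset, weather,
                          constants = model_constants(),
                          metric = c("value", "yield"), co2 = NULL) {
  metric <- match.arg(metric)
  both <- dplyr::bind_rows(
    dplyr::mutate(profile_genotype(profile), genotype = "profile"),
    dplyr::mutate(mean_genotype(dset), genotype = "mean")
  )
  sim <- simulate_crop(both, weather, constants, co2 = co2)
  wide <- tidyr::pivot_wider(
    sim[, c("genotype", "year", metric)],
    names_from = "genotype", values_from = dplyr::all_of(metric)
  )
  if (nrow(wide) < 2L) rlang::abort("need at least 2 years of weather.")
  usable <- wide$mean > 0
  if (!all(usable)) {
    rlang::warn(sprintf(
      "%d year(s) with zero output for the mean genotype excluded from the benefit.",
      sum(!usable)
    ))
  }
  benefit <- 100 * (wide$profile[usable] - wide$mean[usable]) / wide$mean[usable]
  out <- tibble::tibble(
    mean_benefit_pct = mean(benefit),
    sd_benefit_pct = stats::sd(benefit),
    years = sum(usable)
  )
  attr(out, "by_year") <- tibble::tibble(
    year = wide$year[usable], benefit_pct = benefit
  )
  class(out) <- c("benefit_estimate", class(out))
  out
}
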