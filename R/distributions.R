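#' Describe one trait-parameter distribution
#'
#' A trait distribution is the unit of perturbation in an ideotyping study:
#' one model parameter together with its statistical description, either a
#' normal density (mean, sd) or a small set of equiprobable discrete levels
#' (used for ordinal traits such as disease-resistance classes).
#'
#' @param name Parameter identifier; one of [trait_parameter_names()] for the
#'   packaged sets, free text for custom studies.
#' @param family `"normal"` or `"discrete"`.
#' @param mean,sd Mean and standard deviation in trait units (normal family
#'   only; `sd` must be positive).
#' @param levels Strictly increasing numeric levels, drawn with equal
#'   probability (discrete family only).
#' @param units Free-text unit label.
#'
#' @return A one-row tibble with columns `name`, `family`, `mean`, `sd`,
#'   `levels` (list column) and `units`.
#' @examples
#' trait_distribution("RUE", "normal", mean = 2.72, sd = 0.23, units = "g MJ-1")
#' trait_distribution("BlastRes", "discrete", levels = 1:3)
#' @export
trait_distribution <- function(name, family = c("normal", "discrete"),
                               mean = NA_real_, sd = NA_real_,
                               levels = NULL, units = "") {
  family <- match.arg(family)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    rlang::abort("`name` must be a non-empty string.")
  }
  if (family == "normal") {
    .check_number(mean, "mean")
    .check_number(sd, "sd", lower = 0, strict_lower = TRUE)
    levels <- list(NULL)
  } else {
    if (is.null(levels) || length(levels) == 0L) {
      rlang::abort("discrete family requires non-empty `levels`.")
    }
    levels <- as.numeric(levels)
    if (any(!is.finite(levels)) || is.unsorted(levels, strictly = TRUE)) {
      rlang::abort("`levels` must be finite and strictly increasing.")
    }
    mean <- base::mean(levels)
    sd <- NA_real_
    levels <- list(levels)
  }
  tibble::tibble(
    name = name, family = family, mean = mean, sd = sd,
    levels = levels, units = units
  )
}

#' Assemble a set of trait distributions
#'
#' Binds individual [trait_distribution()] rows into one labelled set and
#' checks that names are unique. A *complete* set — required for design
#' sampling — covers each of the nine canonical parameters exactly once.
#'
#' @param ... One-row trait-distribution tibbles (or a single list of them).
#' @param label Set label, e.g. `"germplasm"`, `"literature"`, `"custom"`.
#'
#' @return A tibble of trait distributions with attribute `label`.
#' @seealso [germplasm_distributions()], [literature_distributions()]
#' @export
distribution_set <- function(..., label = "custom") {
  entries <- list(...)
  if (length(entries) == 1L && !is.data.frame(entries[[1L]])) {
    entries <- entries[[1L]]
  }
  out <- dplyr::bind_rows(entries)
  if (nrow(out) == 0L) rlang::abort("empty distribution set.")
  if (anyDuplicated(out$name)) {
    rlang::abort("parameter names must be unique within a distribution set.")
  }
  attr(out, "label") <- label
  out
}

validate_complete_set <- function(dset) {
  missing <- setdiff(.param_names, dset$name)
  extra <- setdiff(dset$name, .param_names)
  if (length(missing) || length(extra)) {
    rlang::abort(paste0(
      "distribution set must cover the 9 canonical parameters exactly once",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", "))
    ))
  }
  dset[match(.param_names, dset$name), , drop = FALSE]
}

.read_dset_json <- function(path, label) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(raw, function(e) {
    trait_distribution(
      name = e$name, family = e$family,
      mean = if (is.null(e$mean)) NA_real_ else e$mean,
      sd = if (is.null(e$sd)) NA_real_ else e$sd,
      levels = if (is.null(e$levels)) NULL else unlist(e$levels),
      units = if (is.null(e$units)) "" else e$units
    )
  })
  distribution_set(entries, label = label)
}

#' Packaged trait-distribution sets
#'
#' The two canonical nine-parameter sets shipped with the package: the
#' germplasm-specific set, whose RUE, k, SLAini and SLAtill distributions were
#' measured on a 43-variety Italian rice panel, and the literature-derived set
#' for rice worldwide. The five stress/quality parameters (blast resistance
#' and four threshold temperatures) are shared between the sets.
#'
#' @return A complete distribution set (tibble of 9 rows).
#' @examples
#' germplasm_distributions()
#' @export
germplasm_distributions <- function() {
  .read_dset_json(
    system.file("extdata", "trait-distributions-germplasm.json",
      package = "ideotypr", mustWork = TRUE
    ),
    label = "germplasm"
  )
}

#' @rdname germplasm_distributions
#' @export
literature_distributions <- function() {
  .read_dset_json(
    system.file("extdata", "trait-distributions-literature.json",
      package = "ideotypr", mustWork = TRUE
    ),
    label = "literature"
  )
}

#' Read or write a distribution set as JSON
#'
#' Serialization mirrors the packaged files: an array of objects with keys
#' `name`, `family`, `mean`, `sd`, `levels`, `units`.
#'
#' @param path File path.
#' @param dset A distribution set tibble.
#' @param label Label for the read set (defaults to the file name).
#' @return `read_distribution_set()` returns the set;
#'   `write_distribution_set()` returns `path` invisibly.
#' @export
read_distribution_set <- function(path, label = basename(path)) {
  .read_dset_json(path, label = label)
}

#' @rdname read_distribution_set
#' @export
write_distribution_set <- function(dset, path) {
  recs <- purrr::pmap(dset, function(name, family, mean, sd, levels, units) {
    out <- list(name = name, family = family, units = units)
    if (family == "normal") {
      out$mean <- mean
      out$sd <- sd
    } else {
      out$levels <- levels
    }
    out
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Fit a normal trait distribution to measured values
#'
#' Sample mean and sample standard deviation (n - 1 denominator), as used to
#' turn a phenotyped variety panel into a germplasm-specific distribution.
#'
#' @param values Numeric vector of at least 3 finite measurements.
#' @param name,units Passed to [trait_distribution()].
#' @return A one-row normal trait distribution.
#' @examples
#' fit_normal(c(28.6, 28.7, 28.8), name = "SLAtill")
#' @export
fit_normal <- function(values, name = "trait", units = "") {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    rlang::abort("fit_normal() needs at least 3 finite values.")
  }
  s <- stats::sd(values)
  if (s == 0) {
    rlang::abort("values have zero variance; a normal fit is degenerate.")
  }
  trait_distribution(name, "normal", mean = mean(values), sd = s, units = units)
}

#' Shapiro-Wilk normality test
#'
#' Thin tidy wrapper around [stats::shapiro.test()], used to check that
#' measured trait values are compatible with a normal distribution before
#' adopting a normal perturbation family.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return A tibble with columns `statistic` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    rlang::abort("shapiro_wilk() requires 3 <= n <= 5000.")
  }
  ht <- stats::shapiro.test(values)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# Sup-difference between two normal CDFs on a fine grid spanning both
# densities, refined with optimize() around the grid maximum.
.ks_two_normals <- function(m1, s1, m2, s2) {
  lo <- min(m1 - 8 * s1, m2 - 8 * s2)
  hi <- max(m1 + 8 * s1, m2 + 8 * s2)
  grid <- seq(lo, hi, length.out = 4001L)
  diffs <- abs(stats::pnorm(grid, m1, s1) - stats::pnorm(grid, m2, s2))
  i <- which.max(diffs)
  window <- grid[c(max(1L, i - 1L), min(length(grid), i + 1L))]
  opt <- stats::optimize(
    function(x) abs(stats::pnorm(x, m1, s1) - stats::pnorm(x, m2, s2)),
    interval = window, maximum = TRUE
  )
  max(diffs[i], opt$objective)
}

.is_dist <- function(x) is.data.frame(x) && all(c("name", "family") %in% names(x))

#' Kolmogorov-Smirnov comparison of samples or normal distributions
#'
#' Compares two trait samples, a sample against a fitted normal, or two normal
#' trait distributions. For two samples (or sample vs. distribution) the
#' statistic and two-sided asymptotic p-value come from [stats::ks.test()].
#' For two theoretical normals the statistic is the closed-form sup-difference
#' of the two CDFs and no p-value is defined (`p_value` is `NA`).
#'
#' @param a,b Numeric samples or one-row normal trait distributions.
#' @return A tibble with columns `D` and `p_value`.
#' @examples
#' ks_compare(
#'   trait_distribution("k", "normal", 0.58, 0.10),
#'   trait_distribution("k", "normal", 0.47, 0.04)
#' )
#' @export
ks_compare <- function(a, b) {
  dist_a <- .is_dist(a)
  dist_b <- .is_dist(b)
  for (d in list(a, b)[c(dist_a, dist_b)]) {
    if (d$family != "normal") {
      rlang::abort("ks_compare() is defined for normal distributions only.")
    }
  }
  if (dist_a && dist_b) {
    d <- .ks_two_normals(a$mean, a$sd, b$mean, b$sd)
    return(tibble::tibble(D = d, p_value = NA_real_))
  }
  if (xor(dist_a, dist_b)) {
    smp <- if (dist_a) b else a
    ref <- if (dist_a) a else b
    if (length(smp) == 0L) rlang::abort("empty sample.")
    ht <- suppressWarnings(stats::ks.test(smp, "pnorm", ref$mean, ref$sd))
  } else {
    if (length(a) == 0L || length(b) == 0L) rlang::abort("empty sample.")
    ht <- suppressWarnings(stats::ks.test(a, b))
  }
  tibble::tibble(D = unname(ht$statistic), p_value = ht$p.value)
}

#' Pairwise Pearson correlations of a trait panel
#'
#' Tests whether measured traits co-vary across varieties; independence (no
#' significant correlation) justifies sampling parameters independently in
#' the sensitivity design.
#'
#' @param panel Trait panel: a data frame with a `variety` column and one
#'   numeric column per measured trait.
#' @return A long tibble with one row per ordered trait pair (diagonal
#'   included, with unit correlation), columns `trait_a`, `trait_b`, `r`,
#'   `p_value`.
#'   Pivoting `r` to wide form gives the symmetric correlation matrix.
#' @export
pearson_correlations <- function(panel) {
  traits <- names(panel)[vapply(panel, is.numeric, logical(1))]
  if (length(traits) < 2L) rlang::abort("need at least two numeric trait columns.")
  complete <- stats::complete.cases(panel[traits])
  dat <- panel[complete, traits, drop = FALSE]
  if (nrow(dat) < 3L) rlang::abort("need at least 3 complete rows.")
  constant <- traits[vapply(dat, function(x) stats::sd(x) == 0, logical(1))]
  if (length(constant)) {
    rlang::abort(paste0(
      "constant trait column(s): ", paste(constant, collapse = ", "),
      "; correlation is undefined."
    ))
  }
  grid <- tidyr::expand_grid(trait_a = traits, trait_b = traits)
  purrr::pmap_dfr(grid, function(trait_a, trait_b) {
    if (trait_a == trait_b) {
      return(tibble::tibble(
        trait_a = trait_a, trait_b = trait_b, r = 1, p_value = NA_real_
      ))
    }
    ht <- stats::cor.test(dat[[trait_a]], dat[[trait_b]], method = "pearson")
    tibble::tibble(
      trait_a = trait_a, trait_b = trait_b,
      r = unname(ht$estimate), p_value = ht$p.value
    )
  })
}

#' Fit normal distributions to every trait of a panel
#'
#' Convenience pipeline step: applies [fit_normal()] to each numeric trait
#' column of a panel and returns the fits as a distribution set.
#'
#' @inheritParams pearson_correlations
#' @param label Label for the resulting set.
#' @return A distribution set tibble (one row per trait).
#' @export
fit_trait_distributions <- function(panel, label = "fitted") {
  traits <- names(panel)[vapply(panel, is.numeric, logical(1))]
  fits <- purrr::map(traits, function(tr) fit_normal(panel[[tr]], name = tr))
  distribution_set(fits, label = label)
}

#' Read or write a trait panel CSV
#'
#' A trait panel holds one row per variety with measured trait values; the
#' canonical header is `variety,RUE,k,SLAini,SLAtill`.
#'
#' @param path File path.
#' @param panel Panel tibble.
#' @return The panel tibble, or `path` invisibly for the writer.
#' @export
read_trait_panel <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"variety" %in% names(out)) rlang::abort("panel CSV needs a `variety` column.")
  out
}

#' @rdname read_trait_panel
#' @export
write_trait_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}
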