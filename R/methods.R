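# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sensitivity result
#'
#' @param x A `sensitivity_result` from [total_order()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `parameter`, `st_raw`, `st`,
#'   `rank`.
#' @export
tidy.sensitivity_result <- function(x, ...) {
  dplyr::arrange(x$st, .data$rank)
}

#' Glance at a sensitivity result
#'
#' @inheritParams tidy.sensitivity_result
#' @return A one-row tibble: `n_parameters`, `base_n`, `variance`,
#'   `top_parameter`.
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x$st),
    base_n = x$base_n %||% NA_integer_,
    variance = x$variance,
    top_parameter = x$st$parameter[x$st$rank == 1L]
  )
}

#' Tidy an ideotype profile
#'
#' @param x An `ideotype_profile` from [derive_profile()].
#' @param ... Unused.
#' @return The profile as a plain tibble.
#' @export
tidy.ideotype_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at an ideotype profile
#'
#' @inheritParams tidy.ideotype_profile
#' @return A one-row tibble: `n_averaged`, `scenario`, `max_abs_deviation_pct`.
#' @export
glance.ideotype_profile <- function(x, ...) {
  tibble::tibble(
    n_averaged = attr(x, "n_averaged"),
    scenario = attr(x, "scenario"),
    max_abs_deviation_pct = max(abs(x$deviation_pct))
  )
}

#' Bar chart of total-order sensitivity indices
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  dat <- tidy(object)
  dat$parameter <- factor(dat$parameter, levels = rev(dat$parameter))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$st, y = .data$parameter)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "Sobol' total-order index",
      y = NULL,
      title = sprintf(
        "Parameter importance (%s)", object$label %||% "sensitivity analysis"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Deviation chart of an ideotype profile
#'
#' Percentage deviation of each ideotype trait from its distribution mean.
#'
#' @param object An `ideotype_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ideotype_profile <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$parameter <- factor(dat$parameter, levels = rev(dat$parameter))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$deviation_pct, y = .data$parameter)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "Deviation from distribution mean (%)", y = NULL,
      title = sprintf(
        "Ideotype profile (%s, top %d combinations)",
        attr(object, "scenario") %||% "study", attr(object, "n_averaged")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Seasonal overview plot of a weather series
#'
#' Daily mean temperature and global radiation against day of year.
#'
#' @param weather A weather tibble.
#' @return A ggplot object.
#' @export
plot_weather <- function(weather) {
  .check_weather(weather)
  dat <- tibble::tibble(
    doy = as.integer(strftime(weather$date, "%j")),
    `mean temperature (degC)` = (weather$tmin + weather$tmax) / 2,
    `global radiation (MJ/m2)` = weather$rad
  )
  long <- tidyr::pivot_longer(dat, -"doy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$doy, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Day of year", y = NULL) +
    ggplot2::theme_minimal()
}
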