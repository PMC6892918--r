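# Study orchestration: the two-arm experiment comparing distribution sets
# (e.g. germplasm-specific vs literature-derived) across climate scenarios.

#' Configure an ideotyping study
#'
#' Collects everything a study needs: the arms (labelled distribution sets
#' compared while holding weather, scenarios and the simulator fixed), the
#' scenario table, the site climate, the design size, the number of weather
#' years, and one master seed from which every stage derives its own seed by
#' a fixed offset.
#'
#' @param arms Named list of complete distribution sets; defaults to the two
#'   packaged sets.
#' @param scenarios Scenario tibble as from [default_scenarios()].
#' @param site A [site_climate()].
#' @param base_n Base points of the radial design (rows = `base_n * 10`);
#'   512 for a full study, 64 for a quick smoke run.
#' @param years Weather years simulated per scenario (20 for a full study).
#' @param seed Master seed (mandatory: studies are reproducible by design).
#' @param constants A [model_constants()] list.
#' @param fraction Top fraction averaged into each ideotype profile.
#' @param metric Output variable for sensitivity and benefits: `"value"`
#'   (euro/ha, default) or `"yield"`.
#' @return A `study_config` list.
#' @export
study_config <- function(arms = list(
                           germplasm = germplasm_distributions(),
                           literature = literature_distributions()
                         ),
                         scenarios = default_scenarios(),
                         site = site_climate(),
                         base_n = 512, years = 20, seed,
                         constants = model_constants(),
                         fraction = 0.01,
                         metric = c("value", "yield")) {
  if (missing(seed)) rlang::abort("a master `seed` is mandatory.")
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    rlang::abort("`arms` must be a named list of distribution sets.")
  }
  metric <- match.arg(metric)
  arms <- purrr::map(arms, validate_complete_set)
  structure(
    list(
      arms = arms, scenarios = tibble::as_tibble(scenarios), site = site,
      base_n = as.integer(base_n), years = as.integer(years),
      seed = as.integer(seed), constants = constants,
      fraction = fraction, metric = metric
    ),
    class = "study_config"
  )
}

# mean output per design row over simulated years, design rows x years in one
# vectorised pass
.evaluate_design <- function(design, weather, constants, metric) {
  sim <- simulate_crop(
    dplyr::mutate(tibble::as_tibble(design), genotype = dplyr::row_number()),
    weather, constants
  )
  agg <- dplyr::summarise(
    dplyr::group_by(sim, .data$genotype),
    out = mean(.data[[metric]]), .groups = "drop"
  )
  agg$out[order(agg$genotype)][seq_len(nrow(design))]
}

#' Run a full ideotyping study
#'
#' For each arm: sample the radial design from its distribution set, simulate
#' every combination over every scenario's weather (all arms share the same
#' underlying weather series), estimate total-order indices on the chosen
#' output, rank the parameters, derive the ideotype profile, and quantify its
#' benefit against the mean genotype. Rankings are then compared across arms
#' with the top-down concordance coefficient, per scenario and averaged.
#' The run is a pure function of `(config)`: identical configurations give
#' bit-identical reports.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, all report tables are
#'   written as CSV/JSON together with a `manifest.json` (seed, sizes,
#'   package version).
#' @return A `study_report` list with tibbles `sensitivity` (arm x scenario
#'   x parameter indices and ranks), `profiles`, `benefits`, `concordance`
#'   (per-scenario TDCC between the first two arms and all arm pairs), the
#'   scalar `average_tdcc`, and `rankings` (list). The `config` is echoed.
#' @examples
#' \donttest{
#' cfg <- study_config(base_n = 64, years = 2, seed = 1,
#'                     scenarios = default_scenarios("baseline"))
#' rep <- run_study(cfg)
#' }
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  weather_base <- generate_weather(
    config$site, config$years,
    seed = derive_seed(config$seed, 1L)
  )
  scen <- config$scenarios
  weathers <- purrr::map(seq_len(nrow(scen)), function(i) {
    apply_scenario(weather_base, scen[i, ])
  })
  names(weathers) <- scen$label

  design_seed <- derive_seed(config$seed, 2L)
  arms <- names(config$arms)
  per_arm <- purrr::map(arms, function(arm) {
    dset <- config$arms[[arm]]
    design <- sample_radial(dset, config$base_n, seed = design_seed)
    per_scen <- purrr::map(scen$label, function(lab) {
      outputs <- .evaluate_design(
        design, weathers[[lab]], config$constants, config$metric
      )
      sr <- total_order(design, outputs)
      prof <- derive_profile(
        design, outputs, sr, dset,
        fraction = config$fraction, scenario = lab
      )
      ben <- yield_benefit(
        prof, dset, weathers[[lab]], config$constants,
        metric = config$metric
      )
      list(sensitivity = sr, profile = prof, benefit = ben)
    })
    names(per_scen) <- scen$label
    list(design = design, scenarios = per_scen)
  })
  names(per_arm) <- arms

  sensitivity <- purrr::map_dfr(arms, function(arm) {
    purrr::map_dfr(scen$label, function(lab) {
      dplyr::mutate(
        per_arm[[arm]]$scenarios[[lab]]$sensitivity$st,
        arm = arm, scenario = lab, .before = 1
      )
    })
  })
  profiles <- purrr::map_dfr(arms, function(arm) {
    purrr::map_dfr(scen$label, function(lab) {
      dplyr::mutate(
        tibble::as_tibble(per_arm[[arm]]$scenarios[[lab]]$profile),
        arm = arm, scenario = lab, .before = 1
      )
    })
  })
  benefits <- purrr::map_dfr(arms, function(arm) {
    purrr::map_dfr(scen$label, function(lab) {
      dplyr::mutate(
        tibble::as_tibble(per_arm[[arm]]$scenarios[[lab]]$benefit),
        arm = arm, scenario = lab, .before = 1
      )
    })
  })
  rankings <- purrr::map(per_arm, function(a) {
    purrr::map(a$scenarios, function(s) ranking(s$sensitivity))
  })

  pairs <- utils::combn(arms, 2, simplify = FALSE)
  concordance <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(scen$label, function(lab) {
      tibble::tibble(
        arm_a = pr[1], arm_b = pr[2], scenario = lab,
        tdcc = tdcc(rankings[[pr[1]]][[lab]], rankings[[pr[2]]][[lab]])
      )
    })
  })
  average_tdcc <- mean(concordance$tdcc)

  report <- structure(
    list(
      sensitivity = sensitivity, profiles = profiles, benefits = benefits,
      concordance = concordance, average_tdcc = average_tdcc,
      rankings = rankings, config = config
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Persist a study report to disk
#'
#' Writes the report tables as CSV, the rankings and concordance as JSON,
#' and a `manifest.json` recording the seed, design size, scenario labels and
#' package version, so a run can be traced and re-executed.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$sensitivity, file.path(out_dir, "sensitivity.csv"))
  readr::write_csv(report$profiles, file.path(out_dir, "profiles.csv"))
  readr::write_csv(report$benefits, file.path(out_dir, "benefits.csv"))
  readr::write_csv(report$concordance, file.path(out_dir, "concordance.csv"))
  jsonlite::write_json(
    list(rankings = report$rankings, average_tdcc = report$average_tdcc),
    file.path(out_dir, "rankings.json"),
    auto_unbox = TRUE, digits = NA
  )
  cfg <- report$config
  jsonlite::write_json(
    list(
      seed = cfg$seed, base_n = cfg$base_n, years = cfg$years,
      arms = names(cfg$arms), scenarios = cfg$scenarios$label,
      metric = cfg$metric, fraction = cfg$fraction,
      package_version = as.character(utils::packageVersion("ideotypr")),
      written = format(Sys.time(), tz = "UTC")
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Ideotyping study: %d arm(s) x %d scenario(s), base_n = %d (%d combinations), %d weather year(s), seed %d\n",
    length(cfg$arms), nrow(cfg$scenarios), cfg$base_n,
    cfg$base_n * 10L, cfg$years, cfg$seed
  ))
  top <- dplyr::filter(x$sensitivity, .data$rank == 1L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf(
      "  [%s | %s] top parameter: %s (ST = %.3f)\n",
      top$arm[i], top$scenario[i], top$parameter[i], top$st[i]
    ))
  }
  cat(sprintf("  average TDCC across arm pairs and scenarios: %.3f\n", x$average_tdcc))
  invisible(x)
}
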