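# Internal helpers shared across modules.

# Canonical parameter names (trait-table order) and their column names in a
# genotype tibble.
.param_names <- c(
  "RUE", "k", "SLAini", "SLAtill", "BlastRes",
  "T-Chalkiness", "T-HeadRice", "T-ColdSter", "T-HeatSter"
)

.param_cols <- c(
  RUE = "rue", k = "k", SLAini = "sla_ini", SLAtill = "sla_till",
  BlastRes = "blast_res", `T-Chalkiness` = "t_chalk",
  `T-HeadRice` = "t_headrice", `T-ColdSter` = "t_coldster",
  `T-HeatSter` = "t_heatster"
)

#' Trait-parameter names used throughout the package
#'
#' The nine model parameters perturbed in an ideotyping study, in canonical
#' order: `RUE`, `k`, `SLAini`, `SLAtill`, `BlastRes`, `T-Chalkiness`,
#' `T-HeadRice`, `T-ColdSter`, `T-HeatSter`.
#'
#' @return Character vector of length 9.
#' @export
trait_parameter_names <- function() .param_names

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    rlang::abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

#' Derive a per-component seed from a master seed
#'
#' One master seed per study, fixed offsets per stage, so every stage
#' (weather, designs, panels) is independently reproducible. The result
#' always stays below 2^31 - 1.
#'
#' @param master Master seed (integer).
#' @param offset Fixed stage offset (integer).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, offset) {
  master <- as.integer(master)
  offset <- as.integer(offset)
  as.integer((as.double(master) * 48271 + as.double(offset) * 7919) %%
    2147483629)
}
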