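# Variance-based global sensitivity analysis: a Gray-code Sobol' sequence
# generator (Joe-Kuo direction numbers, first 20 dimensions) with seeded
# digital-shift scrambling, the radial A / AB_i design, the Jansen
# total-order estimator, and Savage-score rank concordance (TDCC).

# Joe-Kuo "new" direction-number table for dimensions 2..20 (dimension 1 is
# the van der Corput sequence): primitive-polynomial degree s, coefficient a,
# initial direction numbers m.
.sobol_table <- list(
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1, m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)),
  list(s = 6, a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(s = 6, a = 22, m = c(1, 3, 1, 15, 13, 25)),
  list(s = 6, a = 25, m = c(1, 1, 5, 5, 19, 61)),
  list(s = 7, a = 1, m = c(1, 3, 7, 11, 23, 15, 103))
)

.sobol_bits <- 30L

# direction integers V_j * 2^(bits - j) for one dimension
.sobol_directions <- function(dim) {
  bits <- .sobol_bits
  if (dim == 1L) {
    return(bitwShiftL(1L, bits - seq_len(bits)))
  }
  entry <- .sobol_table[[dim - 1L]]
  s <- entry$s
  a <- entry$a
  m <- as.integer(entry$m)
  v <- integer(bits)
  for (j in seq_len(min(s, bits))) {
    v[j] <- bitwShiftL(m[j], bits - j)
  }
  if (bits > s) {
    for (j in (s + 1L):bits) {
      v[j] <- bitwXor(v[j - s], bitwShiftR(v[j - s], s))
      for (kk in seq_len(s - 1L)) {
        if (kk <= s - 1L && bitwAnd(bitwShiftR(a, s - 1L - kk), 1L) == 1L) {
          v[j] <- bitwXor(v[j], v[j - kk])
        }
      }
    }
  }
  v
}

#' Sobol' low-discrepancy sequence
#'
#' First `n` points of a `dim`-dimensional Sobol' sequence (Gray-code
#' construction, Joe-Kuo direction numbers, up to 20 dimensions), optionally
#' randomized by a seeded digital shift (per-dimension XOR with a random
#' 30-bit integer), which preserves the sequence's equidistribution. Points
#' are centred (`(ix + 1/2) / 2^30`) so 0 is never returned and normal
#' quantile mapping stays finite.
#'
#' @param n Number of points.
#' @param dim Number of dimensions (<= 20).
#' @param seed Integer seed for the digital shift; `NULL` for the
#'   unscrambled sequence.
#' @return An `n` x `dim` numeric matrix with entries in (0, 1).
#' @export
sobol_sequence <- function(n, dim, seed = NULL) {
  if (dim > length(.sobol_table) + 1L) {
    rlang::abort(sprintf("sobol_sequence() supports up to %d dimensions.", length(.sobol_table) + 1L))
  }
  bits <- .sobol_bits
  shift <- integer(dim)
  if (!is.null(seed)) {
    shift <- withr::with_seed(
      as.integer(seed),
      as.integer(floor(stats::runif(dim) * 2^bits))
    )
  }
  out <- matrix(0, nrow = n, ncol = dim)
  denom <- 2^bits
  for (d in seq_len(dim)) {
    v <- .sobol_directions(d)
    ix <- 0L
    col <- numeric(n)
    for (i in seq_len(n)) {
      if (i > 1L) {
        # index of the lowest zero bit of i-2 (Gray-code step)
        c0 <- 1L
        val <- i - 2L
        while (bitwAnd(val, 1L) == 1L) {
          val <- bitwShiftR(val, 1L)
          c0 <- c0 + 1L
        }
        ix <- bitwXor(ix, v[c0])
      }
      col[i] <- (bitwXor(ix, shift[d]) + 0.5) / denom
    }
    out[, d] <- col
  }
  out
}

.map_unit_to_trait <- function(u, dist_row) {
  if (dist_row$family == "normal") {
    stats::qnorm(u, dist_row$mean, dist_row$sd)
  } else {
    lv <- dist_row$levels[[1]]
    lv[pmin(length(lv), floor(u * length(lv)) + 1L)]
  }
}

#' Radial Sobol' sampling design over a distribution set
#'
#' Builds the radial design used for total-order estimation: a base matrix A
#' of `base_n` points in the 9-dimensional unit hypercube (Sobol' sequence
#' with seeded digital-shift scrambling; columns 10-18 of the same sequence
#' provide the independent matrix B), plus, for each parameter i, a block
#' AB_i equal to A with column i taken from B — `base_n * (k + 1)` rows in
#' total (5120 for `base_n = 512` and 9 parameters). Unit-cube coordinates
#' are mapped through each parameter's inverse CDF: normal quantile for
#' continuous traits, equal-probability thirds for the 3-level discrete
#' trait.
#'
#' @param dset A complete nine-parameter distribution set.
#' @param base_n Number of base points (>= 2).
#' @param seed Integer seed for the scrambling.
#' @param scramble If `FALSE`, fall back to plain pseudo-random (seeded
#'   `runif`) base points instead of the low-discrepancy sequence.
#' @return A `sobol_design` tibble: provenance columns `base_index` and
#'   `perturbed` (`"A"` for base rows, else the perturbed parameter name)
#'   followed by the nine genotype columns (`rue`, `k`, ...). Attributes:
#'   `param_names`, `base_n`, `label`.
#' @examples
#' d <- sample_radial(germplasm_distributions(), base_n = 8, seed = 1)
#' nrow(d) # 8 * 10
#' @export
sample_radial <- function(dset, base_n, seed, scramble = TRUE) {
  dset <- validate_complete_set(dset)
  if (base_n < 2) rlang::abort("`base_n` must be >= 2.")
  k <- nrow(dset)
  if (scramble) {
    u <- sobol_sequence(base_n, 2L * k, seed = seed)
  } else {
    u <- withr::with_seed(
      as.integer(seed),
      matrix(stats::runif(base_n * 2L * k), nrow = base_n)
    )
  }
  ua <- u[, seq_len(k), drop = FALSE]
  ub <- u[, k + seq_len(k), drop = FALSE]

  blocks <- vector("list", k + 1L)
  unit_blocks <- vector("list", k + 1L)
  unit_blocks[[1L]] <- ua
  for (i in seq_len(k)) {
    m <- ua
    m[, i] <- ub[, i]
    unit_blocks[[i + 1L]] <- m
  }
  perturbed <- c("A", dset$name)
  design <- purrr::map_dfr(seq_along(unit_blocks), function(b) {
    m <- unit_blocks[[b]]
    vals <- purrr::map(seq_len(k), function(i) {
      .map_unit_to_trait(m[, i], dset[i, ])
    })
    names(vals) <- unname(.param_cols[dset$name])
    dplyr::bind_cols(
      tibble::tibble(base_index = seq_len(base_n), perturbed = perturbed[b]),
      tibble::as_tibble(vals)
    )
  })
  # guard against non-physical draws from the normal tails
  cont <- setdiff(unname(.param_cols), "blast_res")
  for (cc in cont) design[[cc]] <- pmax(design[[cc]], 1e-6)
  design$blast_res <- as.integer(design$blast_res)
  attr(design, "param_names") <- dset$name
  attr(design, "base_n") <- as.integer(base_n)
  attr(design, "label") <- attr(dset, "label")
  class(design) <- c("sobol_design", class(design))
  design
}

#' Jansen total-order sensitivity indices on a radial design
#'
#' For each parameter i, the total-order index is estimated as
#' `ST_i = mean((f(A) - f(AB_i))^2) / (2 * V)` with `V` the sample variance
#' of the outputs over the base rows (Jansen estimator). Negative estimates
#' (possible Monte Carlo noise around 0) are clipped to 0 for ranking but
#' reported raw. The ranking is by descending clipped index with an
#' alphabetical tie-break on the parameter name.
#'
#' @param design A [sample_radial()] design.
#' @param outputs Numeric model output, one finite value per design row
#'   (canonically the per-hectare value averaged over simulated years).
#' @return A `sensitivity_result` object: list with elements `st` (tibble
#'   `parameter`, `st_raw`, `st`, `rank`), `variance`, `base_n`, `label`.
#'   Use [tidy()] / [glance()] / [ranking()] / `autoplot()` on it.
#' @export
total_order <- function(design, outputs) {
  if (length(outputs) != nrow(design)) {
    rlang::abort("`outputs` must have one value per design row.")
  }
  if (any(!is.finite(outputs))) rlang::abort("outputs must be finite.")
  params <- attr(design, "param_names") %||% setdiff(
    unique(design$perturbed), "A"
  )
  fa <- outputs[design$perturbed == "A"]
  v <- stats::var(fa)
  if (v <= 0) {
    rlang::abort("zero output variance: the model is degenerate on this design.")
  }
  st_raw <- purrr::map_dbl(params, function(p) {
    fab <- outputs[design$perturbed == p]
    mean((fa - fab)^2) / (2 * v)
  })
  st <- pmax(st_raw, 0)
  ord <- order(-st, params)
  rank <- integer(length(params))
  rank[ord] <- seq_along(params)
  res <- list(
    st = tibble::tibble(parameter = params, st_raw = st_raw, st = st, rank = rank),
    variance = v,
    base_n = attr(design, "base_n"),
    label = attr(design, "label")
  )
  class(res) <- "sensitivity_result"
  res
}

#' Extract the parameter ranking of a sensitivity result
#'
#' @param x A `sensitivity_result`.
#' @return Character vector of parameter names, most influential first
#'   (descending total-order index, alphabetical tie-break).
#' @export
ranking <- function(x) {
  stopifnot(inherits(x, "sensitivity_result"))
  x$st$parameter[order(x$st$rank)]
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "Sobol' total-order sensitivity (%s, base_n = %d, output variance = %.4g)\n",
    x$label %||% "unlabelled", x$base_n %||% NA_integer_, x$variance
  ))
  print(dplyr::arrange(x$st, .data$rank))
  invisible(x)
}

#' Savage scores of a ranking
#'
#' The Savage score of rank r among n items is the tail harmonic sum
#' `sum_{j=r..n} 1/j`; top-ranked items receive the largest scores, which is
#' what makes TDCC emphasize agreement among the most influential
#' parameters.
#'
#' @param ranks Integer ranks (a permutation of `1:n`).
#' @return Numeric vector of Savage scores.
#' @export
savage_scores <- function(ranks) {
  n <- length(ranks)
  if (!setequal(ranks, seq_len(n))) {
    rlang::abort("`ranks` must be a permutation of 1..n (no ties).")
  }
  tail_sums <- rev(cumsum(rev(1 / seq_len(n))))
  tail_sums[ranks]
}

#' Top-down concordance coefficient between two rankings
#'
#' `TDCC = (sum_i SS(r1_i) * SS(r2_i) - n) / (n - sum_{i=1..n} 1/i)` with
#' `SS` the Savage score. Equals 1 iff the rankings are identical; weights
#' disagreements among top-ranked items most heavily.
#'
#' @param r1,r2 Rankings over the same items: character vectors ordered from
#'   most to least important (e.g. from [ranking()]).
#' @return A single number <= 1.
#' @examples
#' tdcc(c("a", "b", "c"), c("c", "b", "a")) # reversed: -0.9286
#' @export
tdcc <- function(r1, r2) {
  if (!setequal(r1, r2) || anyDuplicated(r1) || anyDuplicated(r2)) {
    rlang::abort("rankings must be over the same items, without ties.")
  }
  n <- length(r1)
  items <- sort(r1)
  rank1 <- match(items, r1)
  rank2 <- match(items, r2)
  ss1 <- savage_scores(rank1)
  ss2 <- savage_scores(rank2)
  (sum(ss1 * ss2) - n) / (n - sum(1 / seq_len(n)))
}
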