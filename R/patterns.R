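#' Summary statistics of a final state
#'
#' Two statistics summarise the spatial pattern of behavioural preferences
#' at the end of a run: `p_tot`, the total prevalence of solution s1 among
#' all solvers across the whole population (solver-count weighted), and
#' `p_var`, the spatial variance across sub-populations of the local
#' s1-prevalence among solvers.  Sub-populations with (numerically) no
#' solvers are excluded from the variance, since local prevalence is
#' undefined there.
#'
#' `p_var` treats sub-populations as units.  By default it is the
#' ordinary sample variance across sub-populations (denominator J - 1,
#' as [stats::var()] computes it); this convention, applied to the
#' two-sub-population baseline, reproduces the published classification
#' of the strong-conformity regime as strong local traditions.  Set
#' `var_method = "population"` for the J-denominator population variance,
#' or `weighted = TRUE` for a size-fraction-weighted variance (weighted
#' population form).  With many sub-populations the conventions barely
#' differ; with two they differ by a factor of 2 and can move a run
#' across a classification threshold.
#'
#' @param state A data frame with columns `id`, `s1`, `s2` (local solver
#'   fractions), e.g. from [final_state()], or a `spread_sim` /
#'   `spread_equilibrium` object.
#' @param landscape The [landscape()] the state lives on (ignored when
#'   `state` carries its own).
#' @param weighted Weight the spatial variance by sub-population size
#'   fraction? Default `FALSE`.
#' @param var_method `"sample"` (default, denominator J - 1) or
#'   `"population"` (denominator J); ignored when `weighted = TRUE`.
#' @param solver_eps Sub-populations with `s1 + s2` below this are treated
#'   as solver-free and excluded (default 1e-8).
#' @return A one-row tibble with columns `p_tot`, `p_var`,
#'   `n_patches_included`.
#' @examples
#' st <- tibble::tibble(id = c("P1", "P2"), s1 = c(1, 0), s2 = c(0, 1))
#' summarize_pattern(st, make_two_patch(0.5)$landscape)  # p_var = 0.5
#' @export
summarize_pattern <- function(state, landscape = NULL, weighted = FALSE,
                              var_method = c("sample", "population"),
                              solver_eps = 1e-8) {
  var_method <- match.arg(var_method)
  if (inherits(state, c("spread_sim", "spread_equilibrium"))) {
    landscape <- state$landscape
    state <- final_state(state)
  }
  if (is.null(landscape)) {
    stop("supply a `landscape` (or a simulation object).", call. = FALSE)
  }
  state <- align_state(state, landscape, c("s1", "s2"))
  n <- landscape$sites$size_fraction
  ns <- state$s1 + state$s2
  if (all(ns < solver_eps)) {
    stop("no solvers in any sub-population; pattern statistics undefined.",
         call. = FALSE)
  }
  p_tot <- sum(n * state$s1) / sum(n * ns)
  keep <- ns >= solver_eps
  prev <- state$s1[keep] / ns[keep]
  if (weighted) {
    w <- n[keep] / sum(n[keep])
    mu <- sum(w * prev)
    p_var <- sum(w * (prev - mu)^2)
  } else if (var_method == "sample") {
    p_var <- if (length(prev) > 1) stats::var(prev) else 0
  } else {
    p_var <- mean((prev - mean(prev))^2)
  }
  tibble::tibble(p_tot = p_tot, p_var = p_var,
                 n_patches_included = sum(keep))
}

#' The five emerging-pattern categories
#' @export
pattern_levels <- function() {
  c("mixture", "s2_dominates", "s1_dominates",
    "weak_local_traditions", "strong_local_traditions", "failed")
}

#' Classify the emerging pattern
#'
#' Maps the two summary statistics to one of five categories using fixed
#' thresholds chosen to reflect visual identification of the patterns:
#' spatial variance above 0.1 indicates strong local traditions, between
#' 0.01 and 0.1 weak local traditions; below that, total s1-prevalence
#' above 0.66 means s1 dominated the whole system, below 0.33 s2
#' dominated, and anything else is a mixture of solutions everywhere.
#' Rules are applied in that order with strict inequalities, so an exact
#' boundary value falls through to the next rule (e.g. `p_var = 0.1` is
#' classified as weak local traditions).
#'
#' @param p_tot,p_var Numeric vectors of summary statistics (recycled).
#' @return A factor with levels [pattern_levels()].
#' @examples
#' classify_pattern(c(0.5, 0.7, 0.2, 0.5), c(0.2, 0.001, 0.005, 0.001))
#' @export
classify_pattern <- function(p_tot, p_var) {
  k <- pmax(length(p_tot), length(p_var))
  p_tot <- rep_len(p_tot, k)
  p_var <- rep_len(p_var, k)
  out <- dplyr::case_when(
    is.na(p_tot) | is.na(p_var) ~ "failed",
    p_var > 0.1 ~ "strong_local_traditions",
    p_var > 0.01 ~ "weak_local_traditions",
    p_tot > 0.66 ~ "s1_dominates",
    p_tot < 0.33 ~ "s2_dominates",
    TRUE ~ "mixture"
  )
  factor(out, levels = pattern_levels())
}

#' Phase diagram over conformity strength and movement rate
#'
#' Runs one rescaled-form simulation per (`lambda`, `r`) grid point,
#' classifies the pattern at the end of the horizon, and returns the long
#' table of pixels.  Pixels are independent, so results do not depend on
#' evaluation order; a pixel whose integration fails is recorded with
#' category `"failed"` and `NA` statistics rather than aborting the sweep.
#'
#' @inheritParams simulate_spread
#' @param lambda_grid,r_grid Numeric vectors of parameter values.
#' @param weighted Passed to [summarize_pattern()].
#' @return A tibble of class `phase_diagram` with columns `lambda`, `r`,
#'   `p_tot`, `p_var`, `category`.
#' @examples
#' tp <- make_two_patch(0.5)
#' pd <- phase_diagram(tp$landscape, tp$seeding,
#'                     lambda_grid = c(1, 3.5), r_grid = c(0, 0.35),
#'                     horizon = 150)
#' @export
phase_diagram <- function(landscape, seeding, lambda_grid, r_grid,
                          horizon = 150, weighted = FALSE,
                          atol = 1e-10, rtol = 1e-8) {
  grid <- tidyr::expand_grid(lambda = lambda_grid, r = r_grid)
  res <- purrr::pmap_dfr(grid, function(lambda, r) {
    tryCatch({
      sim <- simulate_spread(landscape, seeding, lambda = lambda, r = r,
                             horizon = horizon, dt = horizon,
                             atol = atol, rtol = rtol)
      summarize_pattern(sim, weighted = weighted)[c("p_tot", "p_var")]
    }, error = function(e) tibble::tibble(p_tot = NA_real_, p_var = NA_real_))
  })
  out <- dplyr::bind_cols(grid, res)
  out$category <- classify_pattern(out$p_tot, out$p_var)
  class(out) <- c("phase_diagram", class(out))
  attr(out, "landscape") <- landscape
  attr(out, "seeding") <- seeding
  attr(out, "horizon") <- horizon
  out
}
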