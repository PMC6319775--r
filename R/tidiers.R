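#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for simulation results
#'
#' `tidy()` returns the long per-sub-population table underlying each
#' result; `glance()` returns a one-row summary including the two pattern
#' statistics and the classified category.
#'
#' @param x A `spread_sim`, `spread_equilibrium`, `calibration_scan` or
#'   `seeding_randomization` object.
#' @param ... Unused.
#' @return A tibble.
#' @name cultspread-tidiers
NULL

#' @rdname cultspread-tidiers
#' @method tidy spread_sim
#' @export
tidy.spread_sim <- function(x, ...) x$trajectory

#' @rdname cultspread-tidiers
#' @method glance spread_sim
#' @export
glance.spread_sim <- function(x, ...) {
  st <- summarize_pattern(x)
  tibble::tibble(
    form = x$form,
    lambda = x$params$lambda,
    r = x$params$r %||% NA_real_,
    alpha = x$params$alpha %||% NA_real_,
    m = x$params$m %||% NA_real_,
    horizon = max(x$trajectory$time),
    p_tot = st$p_tot,
    p_var = st$p_var,
    category = classify_pattern(st$p_tot, st$p_var)
  )
}

#' @rdname cultspread-tidiers
#' @method tidy spread_equilibrium
#' @export
tidy.spread_equilibrium <- function(x, ...) x$state

#' @rdname cultspread-tidiers
#' @method glance spread_equilibrium
#' @export
glance.spread_equilibrium <- function(x, ...) {
  st <- summarize_pattern(x)
  tibble::tibble(
    converged = x$converged,
    stopped_by = x$stopped_by,
    time = x$time,
    max_abs_deriv = x$max_abs_deriv,
    p_tot = st$p_tot,
    p_var = st$p_var,
    category = classify_pattern(st$p_tot, st$p_var)
  )
}

#' @rdname cultspread-tidiers
#' @method tidy calibration_scan
#' @export
tidy.calibration_scan <- function(x, ...) x$surface

#' @rdname cultspread-tidiers
#' @method glance calibration_scan
#' @export
glance.calibration_scan <- function(x, ...) {
  tibble::tibble(
    m_best = x$best$m,
    alpha_best = x$best$alpha,
    ssq_min = x$best$ssq,
    n_grid = nrow(x$surface),
    n_monitored = length(x$monitored_ids),
    n_days = x$n_days
  )
}

#' @rdname cultspread-tidiers
#' @method tidy seeding_randomization
#' @export
tidy.seeding_randomization <- function(x, ...) x$replicates

#' @rdname cultspread-tidiers
#' @method glance seeding_randomization
#' @export
glance.seeding_randomization <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$category_fractions[c("category", "fraction")],
    names_from = "category", values_from = "fraction"
  )
  dplyr::bind_cols(
    tibble::tibble(lambda = x$lambda, r = x$r,
                   n_replicates = x$n_replicates),
    wide
  )
}
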