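#' Extract daily diffusion curves from a simulation
#'
#' The diffusion curve of a monitored sub-population is the proportion of
#' its members that are solvers (of either solution) on each day after
#' release.  Day 1 is the first day after release (`t = 1` on the output
#' grid); set `first_day = 0` to include the release day itself.
#'
#' @param sim A `spread_sim` whose output grid covers the requested days.
#' @param monitored_ids Sub-population ids to extract (default: all).
#' @param n_days Number of days to extract (default 20).
#' @param first_day First day index, 1 (default) or 0.
#' @return A tibble with columns `id`, `day`, `proportion`.
#' @export
extract_diffusion_curves <- function(sim, monitored_ids = NULL,
                                     n_days = 20, first_day = 1) {
  stopifnot(inherits(sim, "spread_sim"))
  traj <- sim$trajectory
  if (is.null(monitored_ids)) monitored_ids <- sim$landscape$sites$id
  missing <- setdiff(monitored_ids, sim$landscape$sites$id)
  if (length(missing) > 0) {
    stop("monitored sub-population not in landscape: ", missing[1],
         call. = FALSE)
  }
  days <- seq(first_day, length.out = n_days)
  if (max(days) > max(traj$time)) {
    stop("simulation horizon (", max(traj$time),
         ") does not cover day ", max(days), ".", call. = FALSE)
  }
  out <- traj[traj$time %in% days & traj$id %in% monitored_ids,
              c("time", "id", "s1", "s2")]
  if (length(unique(out$time)) != n_days) {
    stop("output grid lacks daily points; simulate with `dt = 1`.",
         call. = FALSE)
  }
  tibble::tibble(
    id = out$id,
    day = as.integer(out$time),
    proportion = out$s1 + out$s2
  )[order(match(out$id, monitored_ids), out$time), ]
}

#' Sum-of-squares distance between two diffusion-curve sets
#'
#' Sums, over every monitored location and day, the squared difference
#' between the simulated and empirical proportions of solvers.  The two
#' sets must cover exactly the same (id, day) pairs.
#'
#' @param simulated,empirical Tibbles with columns `id`, `day`,
#'   `proportion` (see [extract_diffusion_curves()]).
#' @return A single non-negative number; 0 iff the curves are identical.
#' @export
curve_ssq <- function(simulated, empirical) {
  key <- function(x) paste(x$id, x$day)
  if (nrow(simulated) != nrow(empirical) ||
      !setequal(key(simulated), key(empirical)) ||
      anyDuplicated(key(simulated)) || anyDuplicated(key(empirical))) {
    stop("simulated and empirical curves must cover the same ",
         "(id, day) pairs exactly once.", call. = FALSE)
  }
  m <- dplyr::inner_join(simulated, empirical, by = c("id", "day"),
                         suffix = c("_sim", "_emp"))
  sum((m$proportion_sim - m$proportion_emp)^2)
}

#' Synthetic "empirical" diffusion curves
#'
#' Generates diffusion curves from the absolute-rate model at known true
#' parameters, optionally adding independent Gaussian observation noise
#' truncated to \[0, 1\].  This is a synthetic stand-in for field-recorded
#' diffusion curves, used to exercise and test the calibration machinery
#' self-containedly; real curves can be supplied to [scan_parameters()]
#' through the same table format (see [read_diffusion_curves()]).
#'
#' @inheritParams simulate_spread
#' @param m_true,alpha_true Generating movement and learning rates.
#' @param noise_sd Observation noise standard deviation (>= 0).
#' @param rng_seed Integer seed; output is deterministic given the seed
#'   and the global RNG state is left untouched.
#' @param monitored_ids Ids to record (default: all).
#' @param n_days,first_day Passed to [extract_diffusion_curves()].
#' @return A tibble with columns `id`, `day`, `proportion`.
#' @export
make_synthetic_empirical <- function(landscape, seeding, m_true, alpha_true,
                                     noise_sd = 0, rng_seed = 1,
                                     monitored_ids = NULL, lambda = 1,
                                     n_days = 20, first_day = 1) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  sim <- simulate_spread(landscape, seeding, lambda = lambda,
                         alpha = alpha_true, m = m_true,
                         horizon = n_days + first_day)
  curves <- extract_diffusion_curves(sim, monitored_ids, n_days, first_day)
  if (noise_sd > 0) {
    noise <- withr::with_seed(rng_seed,
                              stats::rnorm(nrow(curves), 0, noise_sd))
    curves$proportion <- pmin(pmax(curves$proportion + noise, 0), 1)
  }
  curves
}

#' Grid-scan calibration of movement and learning rates
#'
#' Scans a rectangular grid of (`m`, `alpha`) values, simulating the
#' absolute-rate model at each grid point and computing the sum of squares
#' between simulated and empirical diffusion curves over the monitored
#' locations and days present in `empirical`.  The best-fit parameters
#' minimise the sum of squares; ties are broken deterministically in
#' favour of the smallest `m`, then the smallest `alpha`.  Grid points
#' whose integration fails are recorded with `NA` and a warning.  The
#' early diffusion curves depend only on the total solver fractions, which
#' are unaffected by the conformity strength, so `lambda` can be
#' calibrated separately afterwards.
#'
#' @inheritParams simulate_spread
#' @param empirical Tibble with columns `id`, `day`, `proportion`; every
#'   id must exist in the landscape.
#' @param m_range,alpha_range Length-2 ranges scanned (defaults
#'   `c(0, 0.05)` and `c(0, 0.01)`).
#' @param grid_sizes Number of grid points per axis (default `c(11, 11)`).
#' @param first_day Day indexing convention of `empirical` (default 1).
#' @return A `calibration_scan` object: `surface` (tibble `m`, `alpha`,
#'   `ssq`) plus `best` (one-row tibble at the argmin).
#' @examples
#' tp <- make_two_patch(0.5, total_population = 200)
#' emp <- make_synthetic_empirical(tp$landscape, tp$seeding,
#'                                 m_true = 0.025, alpha_true = 0.004)
#' scan_parameters(tp$landscape, tp$seeding, lambda = 1, empirical = emp,
#'                 grid_sizes = c(3, 3))
#' @export
scan_parameters <- function(landscape, seeding, lambda, empirical,
                            m_range = c(0, 0.05), alpha_range = c(0, 0.01),
                            grid_sizes = c(11, 11), first_day = 1) {
  stopifnot(length(m_range) == 2, length(alpha_range) == 2,
            length(grid_sizes) == 2, all(grid_sizes >= 1))
  empirical <- tibble::as_tibble(empirical)
  monitored_ids <- unique(empirical$id)
  n_days <- length(unique(empirical$day))
  grid <- tidyr::expand_grid(
    m = seq(m_range[1], m_range[2], length.out = grid_sizes[1]),
    alpha = seq(alpha_range[1], alpha_range[2], length.out = grid_sizes[2])
  )
  ssq <- purrr::pmap_dbl(grid, function(m, alpha) {
    tryCatch({
      sim <- simulate_spread(landscape, seeding, lambda = lambda,
                             alpha = alpha, m = m,
                             horizon = max(empirical$day))
      curve_ssq(extract_diffusion_curves(sim, monitored_ids, n_days,
                                         first_day),
                empirical)
    }, error = function(e) {
      warning("grid point (m = ", m, ", alpha = ", alpha, ") failed: ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
  })
  surface <- dplyr::bind_cols(grid, ssq = ssq)
  ranked <- surface[order(surface$ssq, surface$m, surface$alpha), ]
  structure(
    list(surface = surface, best = ranked[1, ],
         lambda = lambda, monitored_ids = monitored_ids, n_days = n_days),
    class = "calibration_scan"
  )
}

#' @export
print.calibration_scan <- function(x, ...) {
  cat("<calibration_scan> ", nrow(x$surface), " grid points, ",
      length(x$monitored_ids), " monitored sub-populations, ",
      x$n_days, " days\n", sep = "")
  cat("best fit: m = ", x$best$m, ", alpha = ", x$best$alpha,
      " (ssq = ", format(x$best$ssq, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Read and write diffusion-curve tables
#'
#' Long delimited table with columns `id` (location), `day` (integer) and
#' `proportion` (solvers as a proportion of the sub-population).
#'
#' @param path CSV file path.
#' @param curves Tibble with columns `id`, `day`, `proportion`.
#' @return `read_diffusion_curves()` returns the validated tibble.
#' @export
read_diffusion_curves <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "day", "proportion") %in% names(x))) {
    stop("curve file needs columns id, day, proportion.", call. = FALSE)
  }
  if (any(x$proportion < 0 | x$proportion > 1)) {
    stop("proportions must lie in [0, 1].", call. = FALSE)
  }
  x$id <- as.character(x$id)
  x$day <- as.integer(x$day)
  x
}

#' @rdname read_diffusion_curves
#' @export
write_diffusion_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}
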