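#' Right-hand side of the absolute-rate (baseline) model
#'
#' Time derivatives (per day) of the naive/solver compartments in every
#' sub-population, for the model in absolute counts.  Within sub-population
#' `j`, naive individuals (`U`) learn from local solvers at rate
#' `alpha * (S1 + S2)`, adopting solution s1 with the conformist weight
#' `f_lambda(P)` (where `P` is the local s1-prevalence among solvers) and
#' s2 with the complement; solvers switch preference under the same rates
#' and weights, so the chance of learning from an encounter is independent
#' of whether the learner already holds a preference.  Individuals of every
#' compartment move between sub-populations `j` and `i` at rate
#' `m / d_ji`, proportionally to the destination sub-population size, which
#' keeps every sub-population size constant; with more than two
#' sub-populations the pairwise movement terms are summed over all
#' partners.
#'
#' @param state A data frame with columns `id`, `U`, `S1`, `S2` (counts,
#'   ordered or orderable as `landscape$sites$id`).
#' @param landscape A [landscape()] with `total_population` set.
#' @param lambda Conformity strength (>= 0).
#' @param alpha Learning-rate magnitude (per pair of individuals per day).
#' @param m Movement-rate magnitude (per pair per day per unit distance).
#' @return A tibble with columns `id`, `dU`, `dS1`, `dS2`; within each
#'   sub-population the three derivatives sum to zero.
#' @seealso [rescaled_rhs()], [simulate_spread()]
#' @export
baseline_rhs <- function(state, landscape, lambda, alpha, m) {
  state <- align_state(state, landscape, c("U", "S1", "S2"))
  if (any(state$U < 0 | state$S1 < 0 | state$S2 < 0)) {
    stop("state counts must be non-negative.", call. = FALSE)
  }
  d <- rhs_absolute(
    c(state$U, state$S1, state$S2),
    absolute_parms(landscape, lambda, alpha, m)
  )
  J <- n_patches(landscape)
  tibble::tibble(
    id = landscape$sites$id,
    dU = d[seq_len(J)],
    dS1 = d[J + seq_len(J)],
    dS2 = d[2 * J + seq_len(J)]
  )
}

#' Right-hand side of the rescaled (dimensionless) model
#'
#' Derivatives with respect to rescaled time `tau` of the per-sub-population
#' solver fractions `s1`, `s2` (fractions of the constant local size).  The
#' dynamics depend only on the size fractions `n^(j)`, the distances, the
#' conformity strength `lambda`, and the single compound parameter
#' `r = m / alpha`, the movement rate relative to the learning rate:
#'
#' \deqn{\frac{ds_k^{(j)}}{d\tau} = n^{(j)} n_s^{(j)}
#'   \left[f_\lambda\!\left(\frac{s_k^{(j)}}{n_s^{(j)}}\right) -
#'   s_k^{(j)}\right] +
#'   r \sum_{i \ne j} \frac{n^{(i)}}{d_{ji}} (s_k^{(i)} - s_k^{(j)})}
#'
#' with `n_s = s1 + s2` the local solver fraction.  When a sub-population
#' has (numerically) no solvers (`n_s < 1e-12`) the learning term is set to
#' zero: with no solvers there is nothing to copy, and the 0/0 prevalence
#' never reaches `f_lambda`.
#'
#' @param state A data frame with columns `id`, `s1`, `s2` (fractions).
#' @param landscape A [landscape()] (no `total_population` needed).
#' @param lambda Conformity strength (>= 0).
#' @param r Movement rate relative to the learning rate (>= 0).
#' @return A tibble with columns `id`, `ds1`, `ds2`.
#' @export
rescaled_rhs <- function(state, landscape, lambda, r) {
  state <- align_state(state, landscape, c("s1", "s2"))
  if (any(state$s1 < 0 | state$s2 < 0)) {
    stop("state fractions must be non-negative.", call. = FALSE)
  }
  d <- rhs_rescaled(
    c(state$s1, state$s2),
    rescaled_parms(landscape, lambda, r)
  )
  J <- n_patches(landscape)
  tibble::tibble(
    id = landscape$sites$id,
    ds1 = d[seq_len(J)],
    ds2 = d[J + seq_len(J)]
  )
}

# --- internal flat-vector RHS used by the integrator ---------------------

SOLVER_EPS <- 1e-12

rescaled_parms <- function(landscape, lambda, r) {
  check_lambda(lambda)
  if (r < 0) stop("`r` must be >= 0.", call. = FALSE)
  n <- landscape$sites$size_fraction
  W <- matrix(n, nrow = length(n), ncol = length(n), byrow = TRUE) /
    landscape$distances
  diag(W) <- 0
  list(J = length(n), n = n, W = W, Wrow = rowSums(W),
       lambda = lambda, r = r)
}

rhs_rescaled <- function(y, p) {
  s1 <- y[seq_len(p$J)]
  s2 <- y[p$J + seq_len(p$J)]
  ns <- s1 + s2
  L1 <- numeric(p$J)
  act <- ns >= SOLVER_EPS
  L1[act] <- acquisition_probability(pmin(pmax(s1[act] / ns[act], 0), 1),
                                     p$lambda)
  learn1 <- ifelse(act, p$n * ns * (L1 - s1), 0)
  learn2 <- ifelse(act, p$n * ns * ((1 - L1) - s2), 0)
  move1 <- p$r * (drop(p$W %*% s1) - s1 * p$Wrow)
  move2 <- p$r * (drop(p$W %*% s2) - s2 * p$Wrow)
  unname(c(learn1 + move1, learn2 + move2))
}

absolute_parms <- function(landscape, lambda, alpha, m) {
  check_lambda(lambda)
  if (alpha < 0 || m < 0) stop("`alpha` and `m` must be >= 0.", call. = FALSE)
  if (is.null(landscape$total_population)) {
    stop("absolute-rate runs need `total_population` on the landscape.",
         call. = FALSE)
  }
  N <- landscape$total_population * landscape$sites$size_fraction
  M <- 1 / landscape$distances
  diag(M) <- 0
  list(J = length(N), N = N, M = M, MN = drop(M %*% N),
       lambda = lambda, alpha = alpha, m = m)
}

rhs_absolute <- function(y, p) {
  U <- y[seq_len(p$J)]
  S1 <- y[p$J + seq_len(p$J)]
  S2 <- y[2 * p$J + seq_len(p$J)]
  nS <- S1 + S2
  L1 <- numeric(p$J)
  act <- nS >= SOLVER_EPS
  L1[act] <- acquisition_probability(pmin(pmax(S1[act] / nS[act], 0), 1),
                                     p$lambda)
  L2 <- 1 - L1
  aln <- p$alpha * nS
  dU_l <- -aln * U
  dS1_l <- aln * (L1 * U - L2 * S1 + L1 * S2)
  dS2_l <- aln * (L2 * U - L1 * S2 + L2 * S1)
  mv <- function(X) p$m * (p$N * drop(p$M %*% X) - X * p$MN)
  unname(c(dU_l + mv(U), dS1_l + mv(S1), dS2_l + mv(S2)))
}

align_state <- function(state, landscape, cols) {
  state <- tibble::as_tibble(state)
  need <- c("id", cols)
  if (!all(need %in% names(state))) {
    stop("state needs columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  state$id <- as.character(state$id)
  if (!setequal(state$id, landscape$sites$id) ||
      nrow(state) != n_patches(landscape)) {
    stop("state ids must match the landscape's sub-populations.",
         call. = FALSE)
  }
  state[match(landscape$sites$id, state$id), , drop = FALSE]
}

# --- integration ---------------------------------------------------------

#' Simulate the spread of behavioural preferences
#'
#' Integrates the transmission-plus-movement ODE system from a seeding
#' plan.  Supply `r` to run the rescaled (dimensionless) form in rescaled
#' time `tau`, or both `alpha` and `m` to run the absolute-rate form in
#' days (which requires `total_population` on the landscape).  The system
#' is solved with an adaptive stiff/non-stiff integrator and sampled on a
#' regular output grid (daily by default); the "daily time step" of the
#' study design is a reporting grid, not the integration step.
#'
#' @param landscape A [landscape()].
#' @param seeding A [seeding_plan()] giving initial innovator fractions.
#' @param lambda Conformity strength (>= 0).
#' @param r Movement rate relative to learning rate (rescaled form).
#' @param alpha,m Learning and movement rate magnitudes (absolute form,
#'   per day); mutually exclusive with `r`.
#' @param horizon End of the simulated period (rescaled time units, or
#'   days for the absolute form); default 150.
#' @param dt Output-grid spacing (default 1).
#' @param atol,rtol Absolute and relative integrator tolerances (defaults
#'   1e-10 and 1e-8).
#' @return A `spread_sim` object.  Its `trajectory` element is a tidy
#'   tibble with one row per (time, sub-population): columns `time`, `id`,
#'   `s1`, `s2`, `naive` (fractions of the local sub-population), plus
#'   `U`, `S1`, `S2` counts for absolute-rate runs.  Use [tidy()],
#'   [glance()] and [ggplot2::autoplot()] on it.
#' @examples
#' tp <- make_two_patch(0.5)
#' sim <- simulate_spread(tp$landscape, tp$seeding, lambda = 3.5, r = 0.35)
#' glance(sim)
#' @export
simulate_spread <- function(landscape, seeding, lambda,
                            r = NULL, alpha = NULL, m = NULL,
                            horizon = 150, dt = 1,
                            atol = 1e-10, rtol = 1e-8) {
  if (horizon <= 0) stop("`horizon` must be > 0.", call. = FALSE)
  times <- unique(c(seq(0, horizon, by = dt), horizon))
  out <- integrate_spread(landscape, seeding, lambda, r, alpha, m,
                          times, atol, rtol)
  new_spread_sim(out, landscape,
                 params = list(lambda = lambda, r = r, alpha = alpha, m = m))
}

integrate_spread <- function(landscape, seeding, lambda, r, alpha, m,
                             times, atol, rtol, y0 = NULL) {
  form <- pick_form(r, alpha, m)
  sv <- seeding_vectors(landscape, seeding)
  if (form == "rescaled") {
    p <- rescaled_parms(landscape, lambda, r)
    if (is.null(y0)) y0 <- c(sv$s1, sv$s2)
    f <- function(t, y, parms) list(rhs_rescaled(y, parms))
  } else {
    p <- absolute_parms(landscape, lambda, alpha, m)
    if (is.null(y0)) {
      y0 <- c(p$N * (1 - sv$s1 - sv$s2), p$N * sv$s1, p$N * sv$s2)
    }
    f <- function(t, y, parms) list(rhs_absolute(y, parms))
  }
  sol <- deSolve::ode(y = y0, times = times, func = f, parms = p,
                      method = "lsoda", atol = atol, rtol = rtol)
  if (nrow(sol) < length(times) || anyNA(sol)) {
    istate <- attr(sol, "istate")
    stop("ODE integration failed after t = ", max(sol[, 1]),
         " (istate = ", if (!is.null(istate)) istate[1] else NA,
         "); try looser tolerances.", call. = FALSE)
  }
  y <- clip_negatives(unname(sol[, -1, drop = FALSE]), atol)
  list(times = sol[, 1], y = y, form = form, parms = p)
}

# Round-off can push states a hair below zero; values within integration
# accuracy of zero are clamped at output, anything worse is a real failure.
clip_negatives <- function(y, atol) {
  floor_ <- -100 * atol
  bad <- y < floor_
  if (any(bad)) {
    stop("integration produced a negative state component (",
         format(min(y)), "); not a round-off artefact.", call. = FALSE)
  }
  y[y < 0] <- 0
  y
}

pick_form <- function(r, alpha, m) {
  if (!is.null(r) && is.null(alpha) && is.null(m)) return("rescaled")
  if (is.null(r) && !is.null(alpha) && !is.null(m)) return("absolute")
  stop("supply either `r` (rescaled form) or both `alpha` and `m` ",
       "(absolute form).", call. = FALSE)
}

new_spread_sim <- function(out, landscape, params) {
  ids <- landscape$sites$id
  J <- length(ids)
  base <- tidyr::expand_grid(time = out$times, id = ids)
  if (out$form == "rescaled") {
    traj <- dplyr::mutate(base,
      s1 = as.vector(t(out$y[, seq_len(J), drop = FALSE])),
      s2 = as.vector(t(out$y[, J + seq_len(J), drop = FALSE]))
    )
    traj$naive <- pmax(1 - traj$s1 - traj$s2, 0)
  } else {
    N <- out$parms$N
    traj <- dplyr::mutate(base,
      U = as.vector(t(out$y[, seq_len(J), drop = FALSE])),
      S1 = as.vector(t(out$y[, J + seq_len(J), drop = FALSE])),
      S2 = as.vector(t(out$y[, 2 * J + seq_len(J), drop = FALSE]))
    )
    Nrep <- rep(N, times = length(out$times))
    traj$s1 <- traj$S1 / Nrep
    traj$s2 <- traj$S2 / Nrep
    traj$naive <- traj$U / Nrep
  }
  structure(
    list(trajectory = traj, landscape = landscape, params = params,
         form = out$form),
    class = "spread_sim"
  )
}

#' @export
print.spread_sim <- function(x, ...) {
  cat("<spread_sim> ", x$form, " form, ", n_patches(x$landscape),
      " sub-populations, t in [", min(x$trajectory$time), ", ",
      max(x$trajectory$time), "]\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Final per-sub-population state of a simulation
#'
#' @param sim A `spread_sim` or `spread_equilibrium` object.
#' @return Tibble with columns `id`, `s1`, `s2` (solver fractions of each
#'   sub-population) at the last stored time.
#' @export
final_state <- function(sim) {
  if (inherits(sim, "spread_equilibrium")) return(sim$state[c("id", "s1", "s2")])
  traj <- sim$trajectory
  last <- traj[traj$time == max(traj$time), ]
  last[c("id", "s1", "s2")]
}

#' Integrate to steady state
#'
#' Runs the model forward in chunks until the largest absolute derivative
#' falls below `tol`, or a time cap is reached.  Non-convergence at the
#' cap is reported on the returned object (`converged = FALSE`,
#' `stopped_by = "time_cap"`), never raised as an error, so sweeps can
#' record it.
#'
#' @inheritParams simulate_spread
#' @param tol Convergence tolerance on the maximum absolute derivative
#'   (default 1e-10).
#' @param time_cap Maximum integration time (default 5000).
#' @param chunk Chunk length between convergence checks (default 50).
#' @return A `spread_equilibrium` object with elements `state` (tibble
#'   `id`, `s1`, `s2`, plus `U`, `S1`, `S2` for absolute runs),
#'   `converged`, `stopped_by` (`"derivative_tol"` or `"time_cap"`),
#'   `time`, and `max_abs_deriv`.
#' @examples
#' tp <- make_two_patch(0.5)
#' eq <- steady_state(tp$landscape, tp$seeding, lambda = 3.5, r = 0.35)
#' tidy(eq)
#' @export
steady_state <- function(landscape, seeding, lambda,
                         r = NULL, alpha = NULL, m = NULL,
                         tol = 1e-10, time_cap = 5000, chunk = 50,
                         atol = 1e-10, rtol = 1e-8) {
  form <- pick_form(r, alpha, m)
  t0 <- 0
  y0 <- NULL
  repeat {
    out <- integrate_spread(landscape, seeding, lambda, r, alpha, m,
                            times = c(t0, t0 + chunk), atol, rtol, y0 = y0)
    y0 <- out$y[nrow(out$y), ]
    t0 <- t0 + chunk
    rhs <- if (form == "rescaled") rhs_rescaled(y0, out$parms) else
      rhs_absolute(y0, out$parms)
    mad <- max(abs(rhs))
    if (mad < tol) {
      return(new_spread_equilibrium(y0, out, landscape, TRUE,
                                    "derivative_tol", t0, mad,
                                    list(lambda = lambda, r = r,
                                         alpha = alpha, m = m)))
    }
    if (t0 >= time_cap) {
      return(new_spread_equilibrium(y0, out, landscape, FALSE, "time_cap",
                                    t0, mad,
                                    list(lambda = lambda, r = r,
                                         alpha = alpha, m = m)))
    }
  }
}

new_spread_equilibrium <- function(y, out, landscape, converged, rule, time,
                                   mad, params) {
  ids <- landscape$sites$id
  J <- length(ids)
  if (out$form == "rescaled") {
    state <- tibble::tibble(id = ids, s1 = y[seq_len(J)],
                            s2 = y[J + seq_len(J)])
  } else {
    N <- out$parms$N
    state <- tibble::tibble(
      id = ids,
      U = y[seq_len(J)], S1 = y[J + seq_len(J)], S2 = y[2 * J + seq_len(J)]
    )
    state$s1 <- state$S1 / N
    state$s2 <- state$S2 / N
  }
  structure(
    list(state = state, converged = converged, stopped_by = rule,
         time = time, max_abs_deriv = mad, landscape = landscape,
         params = params, form = out$form),
    class = "spread_equilibrium"
  )
}

#' @export
print.spread_equilibrium <- function(x, ...) {
  cat("<spread_equilibrium> ",
      if (x$converged) "converged" else "NOT converged",
      " (", x$stopped_by, ") at t = ", x$time,
      ", max |deriv| = ", format(x$max_abs_deriv, digits = 3), "\n",
      sep = "")
  print(x$state, n = 5)
  invisible(x)
}
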