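test_that("derivatives vanish without solvers and balance within patches", {
  ls <- random_landscape(3)
  naive_r <- tibble::tibble(id = ls$sites$id, s1 = 0, s2 = 0)
  dr <- rescaled_rhs(naive_r, ls, lambda = 2, r = 0.5)
  expect_equal(dr$ds1, rep(0, 3))
  expect_equal(dr$ds2, rep(0, 3))

  N <- ls$total_population * ls$sites$size_fraction
  naive_a <- tibble::tibble(id = ls$sites$id, U = N, S1 = 0, S2 = 0)
  da <- baseline_rhs(naive_a, ls, lambda = 2, alpha = 0.01, m = 0.02)
  expect_equal(da$dU, rep(0, 3))

  # learning + movement leave each sub-population's size unchanged
  withr::with_seed(5, {
    for (i in 1:20) {
      lsi <- random_landscape(sample(2:5, 1))
      st <- to_absolute_state(random_rescaled_state(lsi), lsi)
      d <- baseline_rhs(st, lsi, lambda = runif(1, 0, 5),
                        alpha = runif(1, 0, 0.01), m = runif(1, 0, 0.05))
      expect_lt(max(abs(d$dU + d$dS1 + d$dS2)), 1e-12 * max(abs(d$dS1), 1))
    }
  })
})

test_that("mirrored states give mirrored derivatives on a symmetric pair", {
  tp <- make_two_patch(0.5)$landscape
  st <- tibble::tibble(id = c("P1", "P2"),
                       s1 = c(0.3, 0.1), s2 = c(0.1, 0.3))
  d <- rescaled_rhs(st, tp, lambda = 2.5, r = 0.7)
  expect_equal(d$ds1[1], d$ds2[2])
  expect_equal(d$ds2[1], d$ds1[2])
})

test_that("rescaled form is the exact rescaling of the baseline form", {
  # mapping: s_k = S_k / N^(j), tau = alpha * N * t, r = m / alpha;
  # checked on random landscapes and states for 2 and 3 sub-populations
  withr::with_seed(17, {
    for (i in 1:50) {
      J <- if (i %% 2 == 0) 2 else 3
      ls <- random_landscape(J, total_population = runif(1, 100, 2000))
      state <- random_rescaled_state(ls)
      lambda <- runif(1, 0, 5)
      alpha <- runif(1, 1e-4, 0.01)
      m <- runif(1, 0, 0.05)
      dr <- rescaled_rhs(state, ls, lambda = lambda, r = m / alpha)
      da <- baseline_rhs(to_absolute_state(state, ls), ls,
                         lambda = lambda, alpha = alpha, m = m)
      N <- ls$total_population * ls$sites$size_fraction
      scale <- N * alpha * ls$total_population
      expect_equal(dr$ds1, da$dS1 / scale, tolerance = 1e-10)
      expect_equal(dr$ds2, da$dS2 / scale, tolerance = 1e-10)
    }
  })
})

test_that("integration conserves sub-population sizes and compartments", {
  ls <- random_landscape(3, total_population = 600)
  plan <- seeding_plan(ls$sites$id[1:2], s1 = c(0.02, 0), s2 = c(0, 0.03))
  sim <- simulate_spread(ls, plan, lambda = 2, alpha = 0.005, m = 0.02,
                         horizon = 150)
  traj <- tidy(sim)
  N <- ls$total_population * ls$sites$size_fraction
  tot <- traj$U + traj$S1 + traj$S2
  expect_lt(max(abs(tot / rep(N, length(unique(traj$time))) - 1)), 1e-8)

  # pure movement (alpha = 0) conserves each compartment globally
  sim0 <- simulate_spread(ls, plan, lambda = 2, alpha = 0, m = 0.02,
                          horizon = 100)
  sums <- dplyr::summarise(dplyr::group_by(tidy(sim0), time),
                           U = sum(U), S1 = sum(S1), S2 = sum(S2))
  expect_lt(max(abs(sums$S1 - sums$S1[1])), 1e-7)
  expect_lt(max(abs(sums$S2 - sums$S2[1])), 1e-7)
  expect_lt(max(abs(sums$U - sums$U[1])), 1e-7)
})

test_that("relabeling the two solutions mirrors the trajectory exactly", {
  tp <- make_three_patch(c(0.5, 0.2, 0.3), distance_P2 = 1.5)
  swapped <- tp$seeding
  names(swapped)[match(c("s1", "s2"), names(swapped))] <- c("s2", "s1")
  a <- simulate_spread(tp$landscape, tp$seeding, lambda = 2.2, r = 0.6,
                       horizon = 80)
  b <- simulate_spread(tp$landscape, swapped, lambda = 2.2, r = 0.6,
                       horizon = 80)
  expect_equal(tidy(a)$s1, tidy(b)$s2, tolerance = 1e-9)
  expect_equal(tidy(a)$s2, tidy(b)$s1, tolerance = 1e-9)
})

test_that("isolated seeded patch fixes its solution; unseeded stays naive", {
  tp <- make_two_patch(0.5, seed_fraction = 0)
  plan <- seeding_plan("P1", s1 = 0.01)
  sim <- simulate_spread(tp$landscape, plan, lambda = 2, r = 0,
                         horizon = 60)
  fin <- final_state(sim)
  expect_equal(fin$s1[fin$id == "P1"], 1, tolerance = 1e-6)
  expect_equal(fin$s1[fin$id == "P2"] + fin$s2[fin$id == "P2"], 0)

  # with lambda > 1 and the rival solution absent globally, spread reaches
  # every connected patch (logistic-like absorption)
  sim2 <- simulate_spread(tp$landscape, plan, lambda = 2, r = 0.5,
                          horizon = 200)
  fin2 <- final_state(sim2)
  expect_true(all(fin2$s1 > 1 - 1e-5))
  expect_true(all(fin2$s2 == 0))
})

test_that("single-population equilibria depend on conformity as expected", {
  one <- single_patch()
  # anti-conformity equalizes solvers regardless of unequal seeds
  eq_lo <- steady_state(one, seeding_plan("P1", s1 = 0.03, s2 = 0.01),
                        lambda = 0.5, r = 0)
  expect_equal(eq_lo$state$s1, 0.5, tolerance = 1e-6)
  expect_equal(eq_lo$state$s2, 0.5, tolerance = 1e-6)

  # proportional copying preserves the seeded ratio: at lambda = 1 both
  # fractions grow as ds_k/dtau = s_k (1 - n_s), so s1/s2 is invariant
  # and the 2:1 seeding ends at prevalence 2/3 (independent closed-form)
  eq_1 <- steady_state(one, seeding_plan("P1", s1 = 0.02, s2 = 0.01),
                       lambda = 1, r = 0)
  prev <- eq_1$state$s1 / (eq_1$state$s1 + eq_1$state$s2)
  expect_equal(prev, 2 / 3, tolerance = 1e-6)

  # conformity drives the initially more common solution to fixation
  eq_hi <- steady_state(one, seeding_plan("P1", s1 = 0.02, s2 = 0.01),
                        lambda = 3, r = 0)
  expect_equal(eq_hi$state$s1, 1, tolerance = 1e-6)
  expect_lt(eq_hi$state$s2, 1e-6)
})

test_that("steady-state search reports its stopping rule honestly", {
  tp <- make_two_patch(0.5)
  eq <- steady_state(tp$landscape, tp$seeding, lambda = 3.5, r = 0.35)
  expect_true(eq$converged)
  expect_identical(eq$stopped_by, "derivative_tol")
  expect_lt(eq$max_abs_deriv, 1e-10)

  capped <- steady_state(tp$landscape, tp$seeding, lambda = 3.5, r = 0.35,
                         tol = 0, time_cap = 10, chunk = 10)
  expect_false(capped$converged)
  expect_identical(capped$stopped_by, "time_cap")
})

test_that("state and parameter validation guards the dynamics", {
  tp <- make_two_patch(0.5)
  bad <- tibble::tibble(id = c("P1", "P2"), s1 = c(-0.1, 0), s2 = c(0, 0))
  expect_error(rescaled_rhs(bad, tp$landscape, 2, 0.5), "non-negative")
  expect_error(
    simulate_spread(tp$landscape, tp$seeding, lambda = 2),
    "either `r`")
  expect_error(
    simulate_spread(tp$landscape, tp$seeding, lambda = 2, r = 1,
                    alpha = 0.1, m = 0.1),
    "either `r`")
  expect_error(
    simulate_spread(tp$landscape, tp$seeding, lambda = 2,
                    alpha = 0.005, m = 0.01),
    "total_population")
})
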