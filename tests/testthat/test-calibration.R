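test_that("diffusion curves report the daily proportion of solvers", {
  tp <- make_two_patch(0.5, total_population = 200)
  # no innovators anywhere: flat zero curves
  naive <- seeding_plan(c("P1", "P2"), s1 = 0, s2 = 0)
  sim0 <- simulate_spread(tp$landscape, naive, lambda = 1,
                          alpha = 0.005, m = 0.01, horizon = 25)
  cv0 <- extract_diffusion_curves(sim0, n_days = 20)
  expect_equal(cv0$proportion, rep(0, 40))
  expect_equal(sort(unique(cv0$day)), 1:20)

  # no movement: the unseeded patch can never gain a solver
  plan <- seeding_plan("P1", s1 = 0.01)
  sim_m0 <- simulate_spread(tp$landscape, plan, lambda = 1,
                            alpha = 0.005, m = 0, horizon = 25)
  cv_m0 <- extract_diffusion_curves(sim_m0, n_days = 20)
  expect_equal(cv_m0$proportion[cv_m0$id == "P2"], rep(0, 20))

  # seeded patch with positive learning: monotone non-decreasing uptake
  expect_true(all(diff(cv_m0$proportion[cv_m0$id == "P1"]) >= 0))

  expect_error(extract_diffusion_curves(sim_m0, "P9"), "P9")
  expect_error(extract_diffusion_curves(sim_m0, n_days = 50), "cover")
})

test_that("curve distance is the summed squared daily difference", {
  base <- tidyr::expand_grid(id = c("A", "B"), day = 1:20)
  flat <- function(v) dplyr::mutate(base, proportion = v)
  expect_equal(curve_ssq(flat(0.2), flat(0.2)), 0)
  # constant offset delta over L locations and D days: L * D * delta^2
  expect_equal(curve_ssq(flat(0.2), flat(0.3)), 2 * 20 * 0.1^2)

  withr::with_seed(8, {
    a <- dplyr::mutate(base, proportion = runif(40))
    b <- dplyr::mutate(base, proportion = runif(40))
  })
  # brute-force double loop over locations and days as the oracle
  acc <- 0
  for (loc in c("A", "B")) for (d in 1:20) {
    acc <- acc + (a$proportion[a$id == loc & a$day == d] -
                  b$proportion[b$id == loc & b$day == d])^2
  }
  expect_equal(curve_ssq(a, b), acc)
  expect_equal(curve_ssq(a, b), curve_ssq(b, a))

  expect_error(curve_ssq(a, b[b$day < 20, ]), "same")
  mismatched <- dplyr::mutate(b, id = ifelse(id == "B", "C", id))
  expect_error(curve_ssq(a, mismatched), "same")
})

test_that("synthetic empirical curves are reproducible and near the model", {
  tp <- make_two_patch(0.5, total_population = 200)
  clean <- make_synthetic_empirical(tp$landscape, tp$seeding,
                                    m_true = 0.02, alpha_true = 0.005)
  sim <- simulate_spread(tp$landscape, tp$seeding, lambda = 1,
                         alpha = 0.005, m = 0.02, horizon = 21)
  expect_equal(clean, extract_diffusion_curves(sim, n_days = 20))

  noisy1 <- make_synthetic_empirical(tp$landscape, tp$seeding, 0.02, 0.005,
                                     noise_sd = 0.02, rng_seed = 42)
  noisy2 <- make_synthetic_empirical(tp$landscape, tp$seeding, 0.02, 0.005,
                                     noise_sd = 0.02, rng_seed = 42)
  expect_identical(noisy1, noisy2)
  # 5-sigma envelope of the stated noise level
  expect_true(all(abs(noisy1$proportion - clean$proportion) < 0.1))
  expect_false(identical(noisy1$proportion, clean$proportion))
})

test_that("grid scan recovers generating parameters", {
  ls <- make_three_patch(c(0.4, 0.35, 0.25), distance_P2 = 1.5,
                         total_population = 300)
  m_grid <- seq(0, 0.05, length.out = 6)     # truth on the grid
  a_grid <- seq(0, 0.01, length.out = 6)
  # generating point chosen in the identifiable corner of the surface:
  # above m ~ 0.02 movement saturates the 20-day curves and the surface
  # flattens in m (see the methods vignette)
  m_true <- m_grid[3]
  a_true <- a_grid[4]
  emp <- make_synthetic_empirical(ls$landscape, ls$seeding, m_true, a_true)
  scan <- scan_parameters(ls$landscape, ls$seeding, lambda = 1,
                          empirical = emp, grid_sizes = c(6, 6))
  # noiseless self-generated data identifies the truth exactly
  expect_equal(scan$best$m, m_true)
  expect_equal(scan$best$alpha, a_true)
  expect_equal(scan$best$ssq, 0, tolerance = 1e-12)
  expect_equal(nrow(scan$surface), 36)

  # small observation noise keeps the argmin within one grid cell
  cell_m <- diff(m_grid)[1]
  cell_a <- diff(a_grid)[1]
  for (rep in 1:10) {
    empn <- make_synthetic_empirical(ls$landscape, ls$seeding,
                                     m_true, a_true,
                                     noise_sd = 0.005, rng_seed = rep)
    sc <- scan_parameters(ls$landscape, ls$seeding, lambda = 1,
                          empirical = empn, grid_sizes = c(6, 6))
    expect_lte(abs(sc$best$m - m_true), cell_m + 1e-12)
    expect_lte(abs(sc$best$alpha - a_true), cell_a + 1e-12)
  }
})

test_that("conformity strength does not affect early diffusion curves", {
  # uptake counts only total solvers; the conformist terms cancel in the
  # sum S1 + S2, so the 20-day curves are lambda-invariant
  ls <- make_three_patch(c(0.4, 0.35, 0.25), distance_P2 = 1.5,
                         total_population = 300)
  emp <- make_synthetic_empirical(ls$landscape, ls$seeding, 0.02, 0.006,
                                  noise_sd = 0.01, rng_seed = 2)
  ssqs <- vapply(c(1, 2, 4), function(l) {
    sim <- simulate_spread(ls$landscape, ls$seeding, lambda = l,
                           alpha = 0.006, m = 0.02, horizon = 21)
    curve_ssq(extract_diffusion_curves(sim, n_days = 20), emp)
  }, numeric(1))
  expect_lt(max(abs(ssqs - ssqs[1])), 1e-8)
})

test_that("diffusion-curve files round-trip and are validated", {
  path <- file.path(withr::local_tempdir(), "curves.csv")
  curves <- tidyr::expand_grid(id = c("F01", "F02"), day = 1:5)
  curves <- dplyr::mutate(curves, proportion = day / 10)
  write_diffusion_curves(curves, path)
  back <- read_diffusion_curves(path)
  expect_equal(back$proportion, curves$proportion)
  bad <- dplyr::mutate(curves, proportion = proportion * 3)
  write_diffusion_curves(bad, path)
  expect_error(read_diffusion_curves(path), "\\[0, 1\\]")
})
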