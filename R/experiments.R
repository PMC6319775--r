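#' Single-population equilibrium portrait
#'
#' With one well-mixed population there is no movement and the dynamics
#' reduce to `ds_k/dtau = n_s [f_lambda(s_k / n_s) - s_k]`.  For each pair
#' of initial innovator fractions this runs the system to steady state and
#' records the equilibrium together with a coarse outcome label:
#' `"equalized"` when both solutions end at 50% of solvers, `"fixation"`
#' when one solution reaches (numerically) all solvers, and
#' `"coexistence"` otherwise — the latter arises at `lambda = 1`, where
#' the final proportions retain the initial ratio.
#'
#' @param lambda Conformity strength (>= 0).
#' @param seed_grid Data frame with columns `s1`, `s2`: initial innovator
#'   fractions (each pair must satisfy `s1 + s2 <= 1`).
#' @param tol Steady-state tolerance (default 1e-10).
#' @param outcome_tol Closeness to 0.5 / 1 used for the outcome label
#'   (default 1e-3).
#' @return A tibble with columns `s1_0`, `s2_0`, `s1_eq`, `s2_eq`,
#'   `prevalence_eq` (s1 among solvers at equilibrium), `converged`,
#'   `outcome`.
#' @examples
#' single_population_portrait(3, tibble::tibble(s1 = 0.02, s2 = 0.01))
#' @export
single_population_portrait <- function(lambda, seed_grid, tol = 1e-10,
                                       outcome_tol = 1e-3) {
  seed_grid <- tibble::as_tibble(seed_grid)
  stopifnot(all(c("s1", "s2") %in% names(seed_grid)))
  one <- landscape(tibble::tibble(id = "P1", size_fraction = 1),
                   matrix(0, 1, 1))
  purrr::pmap_dfr(seed_grid[c("s1", "s2")], function(s1, s2) {
    eq <- steady_state(one, seeding_plan("P1", s1 = s1, s2 = s2),
                       lambda = lambda, r = 0, tol = tol)
    ns <- eq$state$s1 + eq$state$s2
    prev <- if (ns > 0) eq$state$s1 / ns else NA_real_
    outcome <- dplyr::case_when(
      is.na(prev) ~ "no_spread",
      abs(prev - 0.5) < outcome_tol ~ "equalized",
      prev > 1 - outcome_tol | prev < outcome_tol ~ "fixation",
      TRUE ~ "coexistence"
    )
    tibble::tibble(s1_0 = s1, s2_0 = s2,
                   s1_eq = eq$state$s1, s2_eq = eq$state$s2,
                   prevalence_eq = prev, converged = eq$converged,
                   outcome = outcome)
  })
}

#' Randomised-seeding sensitivity analysis
#'
#' Repeats the landscape-scale release experiment with randomised initial
#' conditions: in each replicate, one sub-population is drawn uniformly to
#' receive s1-innovators and a second, distinct sub-population to receive
#' s2-innovators.  Each replicate is run to the horizon and the emerging
#' pattern classified; alongside the pattern, two covariates of the
#' release sites are recorded — the difference in naive-pool size (size
#' fraction of the s1 site minus the s2 site) and the difference in
#' [centrality()] — so that the sensitivity of the outcome to the initial
#' conditions can be examined.
#'
#' @inheritParams simulate_spread
#' @param n_replicates Number of randomised replicates (default 100).
#' @param rng_seed Integer seed; the replicate set is deterministic given
#'   the seed and independent of execution order.
#' @param release_fraction Innovators released as a fraction of the seeded
#'   sub-population (default 0.01, the theoretical convention).
#' @param release_count If non-`NULL`, overrides `release_fraction` with an
#'   absolute innovator count per release site (e.g. 2 individuals, the
#'   field convention); requires `total_population` on the landscape.
#' @return A `seeding_randomization` object with `replicates` (tibble:
#'   `replicate`, `s1_site`, `s2_site`, `p_tot`, `p_var`, `category`,
#'   `naive_pool_diff`, `centrality_diff`) and `category_fractions`.
#' @examples
#' ls <- make_synthetic_grid(12, rng_seed = 1)
#' run_randomized_seeding(ls, lambda = 4, r = 0.5, n_replicates = 3,
#'                        rng_seed = 1, horizon = 100)
#' @export
run_randomized_seeding <- function(landscape, lambda, r,
                                   n_replicates = 100, rng_seed = 1,
                                   release_fraction = 0.01,
                                   release_count = NULL,
                                   horizon = 150) {
  if (n_patches(landscape) < 2) {
    stop("randomised seeding needs at least 2 sub-populations.",
         call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1.", call. = FALSE)
  ids <- landscape$sites$id
  draws <- withr::with_seed(rng_seed, {
    purrr::map(seq_len(n_replicates), function(i) sample(ids, 2))
  })
  cent <- centrality(landscape)
  sizes <- stats::setNames(landscape$sites$size_fraction, ids)
  cvals <- stats::setNames(cent$centrality, cent$id)
  frac_for <- function(site) {
    if (is.null(release_count)) return(release_fraction)
    if (is.null(landscape$total_population)) {
      stop("`release_count` needs `total_population` on the landscape.",
           call. = FALSE)
    }
    min(release_count / (landscape$total_population * sizes[[site]]), 1)
  }
  reps <- purrr::imap_dfr(draws, function(pair, i) {
    plan <- seeding_plan(pair,
                         s1 = c(frac_for(pair[1]), 0),
                         s2 = c(0, frac_for(pair[2])))
    sim <- simulate_spread(landscape, plan, lambda = lambda, r = r,
                           horizon = horizon, dt = horizon)
    st <- summarize_pattern(sim)
    tibble::tibble(
      replicate = i, s1_site = pair[1], s2_site = pair[2],
      p_tot = st$p_tot, p_var = st$p_var,
      category = classify_pattern(st$p_tot, st$p_var),
      naive_pool_diff = unname(sizes[pair[1]] - sizes[pair[2]]),
      centrality_diff = unname(cvals[pair[1]] - cvals[pair[2]])
    )
  })
  fractions <- reps |>
    dplyr::count(category, .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / n_replicates)
  structure(
    list(replicates = reps, category_fractions = fractions,
         lambda = lambda, r = r, n_replicates = n_replicates,
         rng_seed = rng_seed, horizon = horizon),
    class = "seeding_randomization"
  )
}

#' @export
print.seeding_randomization <- function(x, ...) {
  cat("<seeding_randomization> ", x$n_replicates, " replicates, lambda = ",
      x$lambda, ", r = ", format(x$r, digits = 4), "\n", sep = "")
  print(x$category_fractions[x$category_fractions$n > 0, ])
  invisible(x)
}

experiment_registry <- function() {
  c("two_patch_phase", "three_patch_phase", "single_population_portrait",
    "randomized_seeding", "calibration_scan")
}

#' Run a registered experiment and write its artifacts
#'
#' Dispatches to one of the package's canned experiment designs, writes
#' every result table as CSV under `out_dir`, and records a YAML manifest
#' of the parameters actually used (including defaults and the RNG seed)
#' so runs can be reproduced.  Defaults for the sweep ranges are package
#' choices: `lambda` in \[1, 5\] and `r` in \[0, 2\] at 11 points each for
#' the phase sweeps.
#'
#' @param name One of `"two_patch_phase"`, `"three_patch_phase"`,
#'   `"single_population_portrait"`, `"randomized_seeding"`,
#'   `"calibration_scan"`.
#' @param config Named list overriding that experiment's defaults; unknown
#'   keys are an error and are listed explicitly.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the result objects written.
#' @export
run_experiment <- function(name, config = list(), out_dir = ".") {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% experiment_registry()) {
    stop("unknown experiment; registered experiments are: ",
         paste(experiment_registry(), collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- switch(name,
    two_patch_phase = list(size_fraction_1 = 0.5, distance = 1,
                           seed_fraction = 0.01,
                           lambda_grid = seq(1, 5, length.out = 11),
                           r_grid = seq(0, 2, length.out = 11),
                           horizon = 150),
    three_patch_phase = list(size_fractions = rep(1 / 3, 3),
                             distance_P2 = c(1, 1.5, 5),
                             seed_fraction = 0.01,
                             lambda_grid = seq(1, 5, length.out = 11),
                             r_grid = seq(0, 2, length.out = 11),
                             horizon = 150),
    single_population_portrait = list(lambda = c(0.5, 1, 3),
                                      seed_grid = tidyr::expand_grid(
                                        s1 = c(0.01, 0.02, 0.03),
                                        s2 = c(0.01, 0.02, 0.03))),
    randomized_seeding = list(n_sites = 60, landscape_seed = 1,
                              total_population = 1000,
                              lambda = c(1, 1.2, 4), r = 0.01,
                              n_replicates = 100, rng_seed = 1,
                              release_count = 2, horizon = 1050),
    calibration_scan = list(n_sites = 60, landscape_seed = 1,
                            total_population = 1000,
                            m_true = 0.01, alpha_true = 0.007,
                            noise_sd = 0.01, rng_seed = 1,
                            lambda = 1, grid_sizes = c(11, 11),
                            n_monitored = 8)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("invalid config keys for ", name, ": ",
         paste(unknown, collapse = ", "), "; valid keys are: ",
         paste(names(defaults), collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  results <- switch(name,
    two_patch_phase = {
      tp <- make_two_patch(cfg$size_fraction_1, cfg$distance,
                           cfg$seed_fraction)
      pd <- phase_diagram(tp$landscape, tp$seeding, cfg$lambda_grid,
                          cfg$r_grid, cfg$horizon)
      readr::write_csv(pd, file.path(out_dir, "two_patch_phase.csv"))
      list(phase = pd)
    },
    three_patch_phase = {
      purrr::map(stats::setNames(cfg$distance_P2, paste0("d", cfg$distance_P2)),
                 function(d2) {
        tp <- make_three_patch(cfg$size_fractions, d2, cfg$seed_fraction)
        pd <- phase_diagram(tp$landscape, tp$seeding, cfg$lambda_grid,
                            cfg$r_grid, cfg$horizon)
        readr::write_csv(pd, file.path(
          out_dir, sprintf("three_patch_phase_d%s.csv", d2)))
        pd
      })
    },
    single_population_portrait = {
      tab <- purrr::map_dfr(cfg$lambda, function(l) {
        dplyr::mutate(single_population_portrait(l, cfg$seed_grid),
                      lambda = l, .before = 1)
      })
      readr::write_csv(tab, file.path(out_dir, "single_population_portrait.csv"))
      list(portrait = tab)
    },
    randomized_seeding = {
      ls <- make_synthetic_grid(cfg$n_sites, rng_seed = cfg$landscape_seed,
                                total_population = cfg$total_population)
      purrr::map(stats::setNames(cfg$lambda, paste0("lambda", cfg$lambda)),
                 function(l) {
        rs <- run_randomized_seeding(
          ls, lambda = l, r = cfg$r, n_replicates = cfg$n_replicates,
          rng_seed = cfg$rng_seed, release_count = cfg$release_count,
          horizon = cfg$horizon)
        readr::write_csv(rs$replicates, file.path(
          out_dir, sprintf("randomized_seeding_lambda%s.csv", l)))
        rs
      })
    },
    calibration_scan = {
      ls <- make_synthetic_grid(cfg$n_sites, rng_seed = cfg$landscape_seed,
                                total_population = cfg$total_population)
      ids <- ls$sites$id
      seeded <- ids[c(1, length(ids))]
      monitored <- ids[round(seq(1, length(ids),
                                 length.out = cfg$n_monitored))]
      plan <- seeding_plan(seeded, s1 = c(0.01, 0), s2 = c(0, 0.01))
      emp <- make_synthetic_empirical(ls, plan, cfg$m_true, cfg$alpha_true,
                                      noise_sd = cfg$noise_sd,
                                      rng_seed = cfg$rng_seed,
                                      monitored_ids = monitored)
      scan <- scan_parameters(ls, plan, lambda = cfg$lambda,
                              empirical = emp, grid_sizes = cfg$grid_sizes)
      readr::write_csv(scan$surface, file.path(out_dir, "ssq_surface.csv"))
      readr::write_csv(scan$best, file.path(out_dir, "best_fit.csv"))
      list(scan = scan)
    }
  )
  manifest <- list(
    experiment = name,
    package_version = as.character(utils::packageVersion("cultspread")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg[!vapply(cfg, is.data.frame, logical(1))]
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(results)
}
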