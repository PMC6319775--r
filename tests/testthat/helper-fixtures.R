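# Shared fixtures, built in code at test time.

single_patch <- function() {
  landscape(tibble::tibble(id = "P1", size_fraction = 1), matrix(0, 1, 1))
}

# A random valid rescaled state on a landscape (solver fractions summing
# below 1 in every patch).
random_rescaled_state <- function(landscape) {
  J <- nrow(landscape$sites)
  s1 <- runif(J, 0, 0.6)
  s2 <- runif(J, 0, 1) * (1 - s1) * 0.9
  tibble::tibble(id = landscape$sites$id, s1 = s1, s2 = s2)
}

# The matching absolute-count state for the baseline form.
to_absolute_state <- function(state, landscape) {
  N <- landscape$total_population * landscape$sites$size_fraction
  tibble::tibble(
    id = state$id,
    U = N * (1 - state$s1 - state$s2),
    S1 = N * state$s1,
    S2 = N * state$s2
  )
}

# A random small landscape with total population, for oracle checks.
random_landscape <- function(J, total_population = 500) {
  frac <- runif(J, 0.2, 1)
  pts <- matrix(runif(2 * J, 0, 5), ncol = 2)
  d <- as.matrix(dist(pts)) + 0.2  # keep distances away from 0
  diag(d) <- 0
  landscape(
    tibble::tibble(id = paste0("P", seq_len(J)),
                   size_fraction = frac / sum(frac)),
    d,
    total_population = total_population
  )
}
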