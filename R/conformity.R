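#' Conformist acquisition probability
#'
#' Probability that a learner adopts solution s1 as a function of the local
#' prevalence `x` of s1 among solvers, under positive frequency-dependent
#' (conformist) copying of strength `lambda`:
#'
#' \deqn{f_\lambda(x) = \left[(x^{-1} - 1)^\lambda + 1\right]^{-1}}
#'
#' `lambda = 1` gives unbiased, proportional copying (the identity map);
#' `lambda > 1` gives a sigmoidal acquisition curve in which the locally
#' most common solution is disproportionately likely to be copied;
#' `0 < lambda < 1` favours the rarer solution; `lambda = 0` makes both
#' solutions equally likely (constant 1/2) regardless of prevalence.
#'
#' Endpoints are handled by the analytic limits rather than evaluating
#' `1/x`: for `lambda > 0`, `f(0) = 0` and `f(1) = 1`.  At `lambda = 0` the
#' interior value is 1/2 while the endpoints keep the limit convention
#' `f(0) = 0`, `f(1) = 1`; the resulting endpoint discontinuity is
#' deliberate, as `lambda = 0` is a conceptual anchor rather than a regime
#' explored dynamically.
#'
#' @param x Numeric vector of prevalences in \[0, 1\]: the proportion of
#'   s1-users among solvers in the local sub-population.  `x` must be a
#'   well-defined proportion; when there are no solvers at all (0/0) the
#'   caller must guard before calling (see [rescaled_rhs()]).
#' @param lambda Non-negative scalar conformity strength (dimensionless).
#' @return Numeric vector of adoption probabilities in \[0, 1\], same length
#'   as `x`.
#' @examples
#' acquisition_probability(0.3, 1)   # 0.3 -- proportional copying
#' acquisition_probability(0.75, 2)  # 0.9 -- conformist bias
#' acquisition_probability(0.5, 10)  # 0.5 -- symmetry fixed point
#' @seealso [learning_weights()]
#' @export
acquisition_probability <- function(x, lambda) {
  check_lambda(lambda)
  if (!is.numeric(x)) {
    stop("`x` must be numeric.", call. = FALSE)
  }
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop("`x` must lie in [0, 1]; offending value: ", x[bad][1], call. = FALSE)
  }
  out <- numeric(length(x))
  lo <- !is.na(x) & x == 0
  hi <- !is.na(x) & x == 1
  mid <- !is.na(x) & !lo & !hi
  # interior: ((1/x - 1)^lambda + 1)^-1; lambda = 0 collapses to 1/2
  out[mid] <- 1 / ((1 / x[mid] - 1)^lambda + 1)
  out[lo] <- 0
  out[hi] <- 1
  out[is.na(x)] <- NA_real_
  out
}

#' Per-solution conformist learning weights
#'
#' The pair of weights entering the learning terms of the transmission
#' model: the weight for solution s1 is the conformist acquisition
#' probability at the local s1-prevalence, and the weight for s2 is its
#' exact complement, so the two always sum to one.
#'
#' @inheritParams acquisition_probability
#' @param prevalence_s1 Numeric vector: local prevalence of s1 among
#'   solvers, in \[0, 1\].
#' @return A tibble with columns `prevalence_s1`, `L_s1`, `L_s2`.
#' @examples
#' learning_weights(c(0.3, 0.75), lambda = 2)
#' @export
learning_weights <- function(prevalence_s1, lambda) {
  L1 <- acquisition_probability(prevalence_s1, lambda)
  tibble::tibble(
    prevalence_s1 = prevalence_s1,
    L_s1 = L1,
    L_s2 = 1 - L1
  )
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0) {
    stop("`lambda` must be a single non-negative number.", call. = FALSE)
  }
  invisible(lambda)
}
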