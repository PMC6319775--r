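#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

pattern_palette <- function() {
  c(mixture = "grey65", s2_dominates = "#3B6FB6",
    s1_dominates = "#E58606", weak_local_traditions = "#A3D977",
    strong_local_traditions = "#1B7837", failed = "black")
}

#' Plot a simulated trajectory
#'
#' Time courses of the naive fraction and the two solver fractions, one
#' panel per sub-population.
#'
#' @param object A `spread_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spread_sim
#' @export
autoplot.spread_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory[c("time", "id", "naive", "s1", "s2")],
    cols = c("naive", "s1", "s2"),
    names_to = "compartment", values_to = "fraction"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$fraction,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~id) +
    ggplot2::scale_colour_manual(
      values = c(naive = "grey30", s1 = "#E58606", s2 = "#3B6FB6")) +
    ggplot2::labs(x = "time", y = "fraction of sub-population",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase diagram
#'
#' One tile per (`lambda`, `r`) pixel, coloured by the emerging pattern.
#'
#' @param object A `phase_diagram` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda, .data$r,
                                       fill = .data$category)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pattern_palette(), drop = FALSE) +
    ggplot2::labs(x = expression(lambda), y = "r (movement / learning)",
                  fill = "emerging pattern") +
    ggplot2::theme_minimal()
}

#' Plot a calibration sum-of-squares surface
#'
#' @param object A `calibration_scan`.
#' @param ... Unused.
#' @return A ggplot with the best-fit grid point marked.
#' @method autoplot calibration_scan
#' @export
autoplot.calibration_scan <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$alpha, .data$m, fill = .data$ssq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, shape = 4, size = 4,
                        colour = "black") +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(x = expression(alpha), y = "m",
                  fill = "sum of squares") +
    ggplot2::theme_minimal()
}

#' Plot a randomised-seeding summary
#'
#' Replicates in the (`p_tot`, `p_var`) plane, coloured by the classified
#' pattern; horizontal lines mark the tradition thresholds.
#'
#' @param object A `seeding_randomization`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot seeding_randomization
#' @export
autoplot.seeding_randomization <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(.data$p_tot, .data$p_var,
                               colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.01, 0.1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = pattern_palette(), drop = FALSE) +
    ggplot2::labs(x = "total prevalence of s1 among solvers",
                  y = "spatial variance of s1 prevalence",
                  colour = "emerging pattern") +
    ggplot2::theme_minimal()
}
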