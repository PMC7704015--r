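#' Plot simulation-study results
#'
#' TIE and exact-size studies are drawn as a `(pi, gamma)` tile surface
#' coloured by the rejection rate (faceted by test for Monte Carlo studies);
#' power studies as rejection-rate curves over the `gamma1` grid, one line
#' per test, with 3-SE ribbons.
#'
#' @param object A `dallal_study` from [tie_study()], [power_study()] or
#'   [exact_size_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' st <- power_study(c(15, 15), pi = c(0.2, 0.3),
#'                   gamma1 = seq(0.2, 0.9, by = 0.35), R = 100, seed = 1)
#' ggplot2::autoplot(st)
#' @exportS3Method ggplot2::autoplot
autoplot.dallal_study <- function(object, ...) {
  type <- attr(object, "study_type")
  alpha <- attr(object, "alpha")
  df <- tibble::as_tibble(object)
  if (type == "power") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma1, y = .data$power,
                                     colour = .data$test)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = pmax(.data$power - 3 * .data$se, 0),
                     ymax = pmin(.data$power + 3 * .data$se, 1),
                     fill = .data$test), alpha = 0.15, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
      ggplot2::labs(x = expression(gamma[1]), y = "empirical power",
                    colour = "test", fill = "test") +
      ggplot2::theme_minimal()
  } else {
    value <- if (type == "tie") "tie" else "size"
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pi, y = .data$gamma,
                                          fill = .data[[value]])) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(midpoint = alpha, low = "steelblue",
                                    mid = "white", high = "firebrick") +
      ggplot2::labs(x = expression(pi), y = expression(gamma), fill = value) +
      ggplot2::theme_minimal()
    if ("test" %in% names(df)) p <- p + ggplot2::facet_wrap(~test)
    p
  }
}

#' @export
print.dallal_study <- function(x, ...) {
  cat("Simulation study (", attr(x, "study_type"), "), alpha = ",
      attr(x, "alpha"), "\n", sep = "")
  NextMethod()
}
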