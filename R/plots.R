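#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Phase portrait of a macroscopic run
#'
#' Orbit in the (x, y) plane coloured by time, with the classical interior
#' equilibrium marked. For hybrid runs the orbit spirals onto the asymptotic
#' closed orbit as learning completes.
#'
#' @param object A `hybrid_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hybrid_result <- function(object, ...) {
  p <- attr(object, "params")
  eq <- equilibrium_classical(p)
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y, colour = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = eq$x, y = eq$y, shape = 4, size = 3) +
    ggplot2::labs(x = "tumour population x", y = "immune population y",
                  colour = "t",
                  title = sprintf("Lotka-Volterra orbit (mu source: %s)",
                                  attr(object, "mu_kind"))) +
    ggplot2::theme_minimal()
}

#' Learning-functional trace plot
#'
#' @param object A `mu_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mu_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$t, .data$mu)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "t", y = expression(mu(t)),
                  title = sprintf("hiding-learning functional (%s)",
                                  attr(object, "source"))) +
    ggplot2::theme_minimal()
}

#' Snapshots of the two activity distributions along a kinetic run
#'
#' @param object A `kinetic_trajectory`.
#' @param times Times to draw (nearest recorded steps); defaults to five
#'   evenly spaced snapshots.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_trajectory <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- seq(min(object$times), max(object$times), length.out = 5)
  snap <- unique(vapply(times, function(t)
    object$times[which.min(abs(object$times - t))], numeric(1)))
  df <- tidy(object) |> dplyr::filter(.data$t %in% snap)
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$f, colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~t, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "activity u", y = "density f(t, u)") +
    ggplot2::theme_minimal()
}
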