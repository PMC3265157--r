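#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a kinetic trajectory into long format
#'
#' @param x A `kinetic_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `u`, `population`, `f`.
#' @export
tidy.kinetic_trajectory <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(cols = c("f1", "f2"), names_to = "population",
                        values_to = "f") |>
    dplyr::mutate(population = dplyr::recode(.data$population,
                                             f1 = "tumour", f2 = "immune"))
}

#' One-row summary of a kinetic trajectory
#'
#' Reports the mode, horizon, step size, final quadrature masses and the
#' largest absolute mass drift of either population (nonzero drift is
#' expected for the reduced dynamics).
#'
#' @param x A `kinetic_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.kinetic_trajectory <- function(x, ...) {
  md <- mass_drift(x)
  tibble::tibble(
    mode = x$mode,
    n_nodes = x$grid$n_nodes,
    n_times = length(x$times),
    t_end = max(x$times),
    dt = x$dt,
    mass1_final = md$mass1[nrow(md)],
    mass2_final = md$mass2[nrow(md)],
    max_mass_drift = max(abs(c(md$drift1, md$drift2)))
  )
}

#' Tidy a macroscopic run
#'
#' @param x A `hybrid_result`.
#' @param ... Unused.
#' @return A tibble `t`, `x`, `y`, `mu` (plain, class attributes dropped).
#' @export
tidy.hybrid_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("t", "x", "y", "mu")])
}

#' One-row summary of a macroscopic run
#'
#' Includes the drift of the classical first integral H over the run, a
#' conservation diagnostic: ~0 for the classical system, transient for the
#' hybrid system until learning completes.
#'
#' @param x A `hybrid_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.hybrid_result <- function(x, ...) {
  p <- attr(x, "params")
  H <- lv_first_integral(x$x, x$y, p)
  tibble::tibble(
    a = p$a, b = p$b, c = p$c, d = p$d,
    mu_kind = attr(x, "mu_kind"),
    dt = attr(x, "dt"),
    t_end = max(x$t),
    x_final = x$x[nrow(x)],
    y_final = x$y[nrow(x)],
    H_drift = max(abs(H - H[1L]))
  )
}
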