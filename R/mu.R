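#' Hiding-learning functional from two distributions
#'
#' The learning functional mu = 1 - integral of (f1 - f2)^2 over the activity
#' domain: mu = 1 exactly when the immune population has reproduced the
#' tumour population's activity distribution, and decreases with the squared
#' L2 distance between the two. The functional form does not guarantee the
#' squared distance stays below 1; when it exceeds 1 the result is clamped to
#' 0 with a warning, so a running simulation degrades gracefully while
#' surfacing the violation.
#'
#' @param f1,f2 `density_state` objects on a shared grid.
#' @return A number in `[0, 1]`.
#' @examples
#' g <- activity_grid()
#' f <- random_density(g, seed = 1)
#' mu_of_distributions(f, f) # exactly 1
#' @export
mu_of_distributions <- function(f1, f2) {
  stopifnot(inherits(f1, "density_state"), inherits(f2, "density_state"))
  stopifnot_same_grid(f1$grid, f2$grid)
  d2 <- sum(f1$grid$weights * (f1$values - f2$values)^2)
  mu <- 1 - d2
  if (mu < 0) {
    warning(sprintf(
      "squared L2 distance %.4g exceeds 1; mu clamped to 0.", d2),
      call. = FALSE)
    mu <- 0
  }
  mu
}

#' Closed-form learning functional for the equal-rate delta dynamics
#'
#' For the Gaussian reference difference profile evolving under equal-rate
#' Dirac-delta kernels, the squared L2 distance has the closed form
#' `exp(-4 eta t) / sqrt(2 pi)`, giving
#' `mu(t) = 1 - exp(-4 eta t) / sqrt(2 pi)`: strictly increasing in t for
#' eta > 0 and converging to 1 (complete learning).
#'
#' @param t Time(s), >= 0 (vectorised).
#' @param eta Common encounter rate, >= 0.
#' @return mu value(s) in `[0, 1]`.
#' @examples
#' mu_closed_form(0, 1 / 4)   # 1 - 1/sqrt(2*pi)
#' mu_closed_form(100, 1 / 4) # ~ 1
#' @export
mu_closed_form <- function(t, eta) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be nonnegative and finite.", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 0)
    stop("`eta` must be a single nonnegative rate.", call. = FALSE)
  1 - exp(-4 * eta * t) / sqrt(2 * pi)
}

#' Quadrature-vs-closed-form consistency of mu
#'
#' Propagates the Gaussian reference difference analytically to each
#' requested time, computes `1 - integral of f(t, u)^2` by quadrature, and
#' compares with [mu_closed_form()]. The maximum absolute discrepancy
#' measures the quadrature error of the grid for this integrand (the domain
#' truncation and Simpson error), and shrinks monotonically under grid
#' refinement.
#'
#' @param d0 A `difference_state`, normally [gaussian_profile()].
#' @param eta Common encounter rate.
#' @param times Times at which to compare.
#' @return Maximum absolute discrepancy over `times`.
#' @export
mu_consistency_check <- function(d0 = gaussian_profile(), eta = 1 / 4,
                                 times = c(0, 1, 2, 4)) {
  stopifnot(inherits(d0, "difference_state"))
  disc <- vapply(times, function(t) {
    ft <- analytic_difference(d0, eta, t)
    mu_quad <- 1 - sum(d0$grid$weights * ft$values^2)
    abs(mu_quad - mu_closed_form(t, eta))
  }, numeric(1))
  max(disc)
}

#' Learning-functional trace along a kinetic trajectory
#'
#' Evaluates [mu_of_distributions()] at every recorded time of a kinetic
#' run. Clamping events are counted in the `clamped` attribute.
#'
#' @param traj A `kinetic_trajectory`.
#' @return A `mu_trace`: tibble with columns `t`, `mu` and attributes
#'   `source = "from_distributions"` and `clamped`.
#' @export
mu_trace <- function(traj) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  w <- traj$grid$weights
  d2 <- as.vector(crossprod((traj$f1 - traj$f2)^2, w))
  clamped <- sum(d2 > 1)
  if (clamped > 0)
    warning(sprintf("mu clamped to 0 at %d of %d times.", clamped, length(d2)),
            call. = FALSE)
  new_mu_trace(traj$times, pmax(1 - d2, 0), source = "from_distributions",
               clamped = clamped)
}

#' Closed-form learning-functional trace
#'
#' @param times Increasing times, >= 0.
#' @param eta Common encounter rate.
#' @return A `mu_trace` with `source = "closed_form"`.
#' @export
mu_trace_closed_form <- function(times, eta) {
  new_mu_trace(times, mu_closed_form(times, eta), source = "closed_form",
               clamped = 0L)
}

new_mu_trace <- function(times, values, source, clamped = 0L) {
  stopifnot(length(times) == length(values), all(diff(times) > 0),
            all(values >= 0), all(values <= 1 + 1e-12))
  out <- tibble::tibble(t = times, mu = pmin(values, 1))
  class(out) <- c("mu_trace", class(out))
  attr(out, "source") <- source
  attr(out, "clamped") <- clamped
  out
}

#' Write a mu trace to CSV
#'
#' Two columns `t`, `mu`; the source tag goes in a `#`-comment header line.
#'
#' @param trace A `mu_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mu_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", attr(trace, "source") %||% "unknown"), con)
  utils::write.csv(as.data.frame(trace[, c("t", "mu")]), con, row.names = FALSE)
  invisible(path)
}

#' Recover the learning rate from a kinetic run
#'
#' Under equal-rate delta dynamics the squared L2 distance decays as
#' `D(t) = D(0) exp(-k t)` with `k = 4 eta`. This fits the log of the
#' observed squared distance along a trajectory by least squares and reports
#' the decay constant and the implied encounter rate `eta = k / 4`.
#'
#' @param traj A `kinetic_trajectory` (delta mode, equal rates, for the
#'   exponential model to hold exactly).
#' @return A one-row tibble with columns `k`, `eta`, `r_squared`, `n_times`.
#' @export
fit_learning_rate <- function(traj) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  w <- traj$grid$weights
  d2 <- as.vector(crossprod((traj$f1 - traj$f2)^2, w))
  keep <- d2 > 0
  y <- log(d2[keep])
  fit <- stats::lm(y ~ traj$times[keep])
  k <- -unname(stats::coef(fit)[2L])
  # direct R^2: summary.lm warns on near-perfect fits, which are the norm here
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  tibble::tibble(k = k, eta = k / 4, r_squared = r2, n_times = sum(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
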