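#' Activity distribution of one population
#'
#' Wraps the values of a probability density f_i(t, u) sampled on an activity
#' grid at one instant. A proper density is nonnegative with unit quadrature
#' mass; construction checks both. Densities whose pointwise values exceed 1
#' are legitimate on narrow supports, so that is reported as a warning, never
#' an error.
#'
#' @param grid An [activity_grid()].
#' @param values Numeric vector of per-node density values.
#' @param time Nonnegative time stamp.
#' @param normalized If `TRUE` (default) require the quadrature mass to be 1
#'   within `tol` (relative) and values to be nonnegative; use `FALSE` for
#'   intermediate un-normalised states.
#' @param tol Relative tolerance on the unit-mass check.
#' @return An object of class `density_state`.
#' @seealso [renormalize()], [random_density()], [difference_state()]
#' @export
density_state <- function(grid, values, time = 0, normalized = TRUE, tol = 1e-6) {
  if (!is_activity_grid(grid)) stop("`grid` must be an activity_grid.", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != grid$n_nodes)
    stop("`values` must have one entry per grid node.", call. = FALSE)
  if (!all(is.finite(values))) stop("`values` must all be finite.", call. = FALSE)
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0)
    stop("`time` must be a single nonnegative number.", call. = FALSE)
  if (normalized) {
    if (any(values < 0))
      stop("a normalized density must be nonnegative everywhere.", call. = FALSE)
    mass <- sum(grid$weights * values)
    if (abs(mass - 1) > tol)
      stop(sprintf("density mass is %.8g, not 1 within tolerance %g; use renormalize().",
                   mass, tol), call. = FALSE)
    if (any(values > 1 + 1e-12))
      warning("density exceeds 1 pointwise (allowed for narrow supports).",
              call. = FALSE)
  }
  structure(list(grid = grid, values = values, time = time,
                 normalized = normalized),
            class = "density_state")
}

#' @export
print.density_state <- function(x, ...) {
  cat(sprintf("<density_state> t = %g, mass = %.6f, %d nodes on [%g, %g]\n",
              x$time, sum(x$grid$weights * x$values),
              x$grid$n_nodes, x$grid$lower, x$grid$upper))
  invisible(x)
}

#' Rescale a state to unit quadrature mass
#'
#' @param f A `density_state`.
#' @return A `density_state` with quadrature mass exactly 1.
#' @export
renormalize <- function(f) {
  stopifnot(inherits(f, "density_state"))
  mass <- sum(f$grid$weights * f$values)
  if (mass <= 0) stop("cannot renormalize a state with nonpositive mass.", call. = FALSE)
  density_state(f$grid, f$values / mass, time = f$time, normalized = TRUE)
}

#' Signed difference of two activity distributions
#'
#' The difference state f = f1 - f2 drives the hiding-learning functional:
#' under Dirac-delta kernels with all four encounter rates equal it decays
#' linearly, df/dt = -2 eta f.
#'
#' @param f1,f2 `density_state` objects on the same grid and at the same time.
#' @return An object of class `difference_state` (values may be negative).
#' @export
difference_state <- function(f1, f2) {
  stopifnot(inherits(f1, "density_state"), inherits(f2, "density_state"))
  stopifnot_same_grid(f1$grid, f2$grid)
  new_difference_state(f1$grid, f1$values - f2$values, time = f1$time)
}

new_difference_state <- function(grid, values, time = 0) {
  structure(list(grid = grid, values = as.numeric(values), time = time),
            class = "difference_state")
}

#' @export
print.difference_state <- function(x, ...) {
  cat(sprintf("<difference_state> t = %g, sup|f| = %.6g, %d nodes\n",
              x$time, max(abs(x$values)), x$grid$n_nodes))
  invisible(x)
}

#' Gaussian reference difference profile
#'
#' The initial difference profile f(0, u) = exp(-u^2) / sqrt(pi): a unit-mass
#' Gaussian used as the reference initial condition for the equal-rate
#' Dirac-delta dynamics and the closed-form learning functional.
#'
#' @param grid An [activity_grid()].
#' @return A `difference_state` at time 0.
#' @examples
#' d0 <- gaussian_profile(activity_grid())
#' grid_integrate(d0$grid, d0$values) # ~ 1
#' @export
gaussian_profile <- function(grid = activity_grid()) {
  if (!is_activity_grid(grid)) stop("`grid` must be an activity_grid.", call. = FALSE)
  new_difference_state(grid, exp(-grid$nodes^2) / sqrt(pi), time = 0)
}

#' Seeded random normalised density (test fixture)
#'
#' Draws a smooth strictly positive random density: a softplus-tempered
#' random Fourier series on the domain, renormalised to unit quadrature mass.
#' Deterministic for a given seed.
#'
#' @param grid An [activity_grid()].
#' @param seed Integer seed.
#' @return A normalised `density_state` at time 0.
#' @export
random_density <- function(grid, seed = 1L) {
  if (!is_activity_grid(grid)) stop("`grid` must be an activity_grid.", call. = FALSE)
  vals <- eval_with_seed(seed, {
    u <- (grid$nodes - grid$lower) / (grid$upper - grid$lower) # in [0, 1]
    y <- rep(0, length(u))
    for (k in 1:4) {
      y <- y + stats::rnorm(1, sd = 1 / k) * sin(2 * pi * k * u) +
        stats::rnorm(1, sd = 1 / k) * cos(2 * pi * k * u)
    }
    log1p(exp(y)) + 1e-3 # strictly positive, smooth
  })
  vals <- vals / sum(grid$weights * vals)
  density_state(grid, vals, time = 0, normalized = TRUE, tol = 1e-12)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
eval_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @export
as_tibble.density_state <- function(x, ...) {
  tibble::tibble(u = x$grid$nodes, value = x$values)
}

#' @export
as_tibble.difference_state <- function(x, ...) {
  tibble::tibble(u = x$grid$nodes, value = x$values)
}

#' Write a density or difference state to CSV
#'
#' Two columns, `u` and `value`, with a header line.
#'
#' @param x A `density_state` or `difference_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
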