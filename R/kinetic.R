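#' @name kinetic_rhs
#' @title Right-hand sides of the kinetic evolution equations
#'
#' @description
#' Time derivatives of the two activity distributions under binary
#' interactions, in three forms:
#'
#' * `rhs_general()` — the full collision balance for a tabulated kernel:
#'   for each population i and outgoing activity u, the gain is
#'   `sum_j eta_ij * double-integral of phi_ij(u_cand, u_field, u) *
#'   f_i(u_cand) * f_j(u_field)` (tensor-product Simpson quadrature) and the
#'   loss is `f_i(u) * sum_j eta_ij * integral of f_j`.
#' * `rhs_separable()` — the factorised form: the gain for population 1 is
#'   `eta_12 * (int psi_1(u_cand, u) f1(u_cand)) * (int xi_2(u_field, u)
#'   f2(u_field))` and symmetrically for population 2. In mode
#'   `"separable_full"` the loss keeps the actual masses `int f_j du`; in
#'   mode `"separable_reduced"` the unit-mass constraint is substituted, so
#'   the loss coefficient is the constant `eta_i1 + eta_i2`. The two modes
#'   coincide while both masses equal 1 and drift apart otherwise; the drift
#'   is diagnosed, not hidden (see [mass_drift()]).
#' * `rhs_delta()` — the Dirac-delta local reduction: `df1 = eta_12 f1 f2 -
#'   (eta_11 + eta_12) f1`, `df2 = eta_21 f1 f2 - (eta_21 + eta_22) f2`,
#'   pointwise in u.
#'
#' @param f1,f2 `density_state` objects on a shared grid.
#' @param kernel A `transition_kernel` (general) or `separable_kernel`.
#' @param rates An [encounter_rates()] matrix.
#' @param mode For `rhs_separable()`: `"separable_full"` or
#'   `"separable_reduced"`.
#' @return A list with numeric vectors `df1`, `df2` (per-node derivatives).
NULL

#' @rdname kinetic_rhs
#' @export
rhs_general <- function(f1, f2, kernel, rates) {
  stopifnot(inherits(kernel, "transition_kernel"),
            inherits(rates, "encounter_rates"))
  stopifnot_same_grid(f1$grid, f2$grid)
  stopifnot_same_grid(f1$grid, kernel$grid)
  g <- f1$grid
  rhs_general_raw(f1$values, f2$values, kernel, rates, g)
}

rhs_general_raw <- function(v1, v2, kernel, rates, grid) {
  n <- grid$n_nodes
  w <- grid$weights
  eta <- rates$eta
  fv <- list(v1, v2)
  mass <- c(sum(w * v1), sum(w * v2))
  gain <- list(rep(0, n), rep(0, n))
  for (i in 1:2) for (j in 1:2) {
    comp <- kernel$components[[paste0("phi", i, j)]]
    if (is.null(comp) || eta[i, j] == 0) next
    # gain_i(u_m) += eta_ij * sum_{a,b} w_a w_b phi[a,b,m] f_i(a) f_j(b)
    vab <- as.vector(outer(w * fv[[i]], w * fv[[j]]))
    gain[[i]] <- gain[[i]] + eta[i, j] * as.vector(crossprod(matrix(comp, n * n, n), vab))
  }
  loss1 <- v1 * (eta[1, 1] * mass[1] + eta[1, 2] * mass[2])
  loss2 <- v2 * (eta[2, 1] * mass[1] + eta[2, 2] * mass[2])
  list(df1 = gain[[1]] - loss1, df2 = gain[[2]] - loss2)
}

#' @rdname kinetic_rhs
#' @export
rhs_separable <- function(f1, f2, kernel, rates,
                          mode = c("separable_full", "separable_reduced")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kernel, "separable_kernel"),
            inherits(rates, "encounter_rates"))
  stopifnot_same_grid(f1$grid, f2$grid)
  stopifnot_same_grid(f1$grid, kernel$grid)
  rhs_separable_raw(f1$values, f2$values, kernel, rates, f1$grid, mode)
}

rhs_separable_raw <- function(v1, v2, kernel, rates, grid, mode) {
  w <- grid$weights
  eta <- rates$eta
  # (int psi_i(u_cand, u) f_i(u_cand) du_cand) as a function of u
  p1 <- as.vector(crossprod(kernel$psi[[1]], w * v1))
  p2 <- as.vector(crossprod(kernel$psi[[2]], w * v2))
  x1 <- as.vector(crossprod(kernel$xi[[1]], w * v1))
  x2 <- as.vector(crossprod(kernel$xi[[2]], w * v2))
  gain1 <- eta[1, 2] * p1 * x2
  gain2 <- eta[2, 1] * p2 * x1
  if (mode == "separable_full") {
    m1 <- sum(w * v1); m2 <- sum(w * v2)
    loss1 <- v1 * (eta[1, 1] * m1 + eta[1, 2] * m2)
    loss2 <- v2 * (eta[2, 1] * m1 + eta[2, 2] * m2)
  } else {
    loss1 <- (eta[1, 1] + eta[1, 2]) * v1
    loss2 <- (eta[2, 1] + eta[2, 2]) * v2
  }
  list(df1 = gain1 - loss1, df2 = gain2 - loss2)
}

#' @rdname kinetic_rhs
#' @export
rhs_delta <- function(f1, f2, rates) {
  stopifnot(inherits(rates, "encounter_rates"))
  stopifnot_same_grid(f1$grid, f2$grid)
  rhs_delta_raw(f1$values, f2$values, rates)
}

rhs_delta_raw <- function(v1, v2, rates) {
  eta <- rates$eta
  list(df1 = eta[1, 2] * v1 * v2 - (eta[1, 1] + eta[1, 2]) * v1,
       df2 = eta[2, 1] * v1 * v2 - (eta[2, 1] + eta[2, 2]) * v2)
}

# --- fixed-step RK4 ---------------------------------------------------------

# march y' = f(t, y) from y0 over `times` (uniform steps); f returns a numeric
# vector. Returns a (length(times) x length(y0)) matrix of states. Aborts with
# the failure time if the state goes non-finite.
rk4_march <- function(f, y0, times, record = TRUE) {
  nt <- length(times)
  y <- y0
  out <- if (record) matrix(NA_real_, nt, length(y0)) else NULL
  if (record) out[1L, ] <- y
  for (s in seq_len(nt - 1L)) {
    t0 <- times[s]
    h <- times[s + 1L] - t0
    k1 <- f(t0, y)
    k2 <- f(t0 + h / 2, y + h / 2 * k1)
    k3 <- f(t0 + h / 2, y + h / 2 * k2)
    k4 <- f(t0 + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y)))
      stop(sprintf("state became non-finite at t = %g.", times[s + 1L]),
           call. = FALSE)
    if (record) out[s + 1L, ] <- y
  }
  if (record) out else y
}

# --- time evolution ---------------------------------------------------------

#' Evolve the two activity distributions in time
#'
#' Integrates the kinetic equations with classical fixed-step fourth-order
#' Runge-Kutta, recording every accepted step. The kernel argument must match
#' the mode: a `transition_kernel` for `"general"`, a `separable_kernel` for
#' the two separable modes, and a [delta_kernel()] (or `NULL`) for
#' `"delta_reduced"`, which uses the analytically reduced local equations.
#'
#' @param f1_0,f2_0 Initial `density_state`s on a shared grid (a state that is
#'   identically zero is allowed and propagates exactly).
#' @param mode One of `"general"`, `"separable_full"`, `"separable_reduced"`,
#'   `"delta_reduced"`.
#' @param kernel Kernel object matching the mode (ignored for
#'   `"delta_reduced"`).
#' @param rates An [encounter_rates()].
#' @param t_end Final time (> 0).
#' @param dt Step size (> 0); the last step is shortened so the final
#'   recorded time is `t_end`.
#' @return A `kinetic_trajectory`: list with `times`, state matrices `f1`,
#'   `f2` (nodes x times), the `grid`, `mode`, `rates` and `dt`.
#' @examples
#' g <- activity_grid(n_nodes = 61)
#' base <- random_density(g, seed = 2)
#' d0 <- gaussian_profile(g)
#' f1 <- density_state(g, base$values + d0$values, normalized = FALSE)
#' traj <- evolve(f1, base, mode = "delta_reduced",
#'                rates = encounter_rates(1 / 4), t_end = 1, dt = 0.05)
#' @export
evolve <- function(f1_0, f2_0, mode = c("general", "separable_full",
                                        "separable_reduced", "delta_reduced"),
                   kernel = NULL, rates, t_end, dt) {
  mode <- match.arg(mode)
  stopifnot(inherits(f1_0, "density_state"), inherits(f2_0, "density_state"),
            inherits(rates, "encounter_rates"))
  stopifnot_same_grid(f1_0$grid, f2_0$grid)
  if (!is.numeric(dt) || dt <= 0 || !is.numeric(t_end) || t_end <= 0)
    stop("`dt` and `t_end` must be positive.", call. = FALSE)
  grid <- f1_0$grid
  n <- grid$n_nodes

  deriv <- switch(
    mode,
    general = {
      stopifnot(inherits(kernel, "transition_kernel"))
      stopifnot_same_grid(grid, kernel$grid)
      function(t, y) {
        d <- rhs_general_raw(y[1:n], y[(n + 1):(2 * n)], kernel, rates, grid)
        c(d$df1, d$df2)
      }
    },
    delta_reduced = {
      if (!is.null(kernel) && !inherits(kernel, "delta_kernel"))
        stop("`delta_reduced` mode takes a delta_kernel() (or NULL).", call. = FALSE)
      function(t, y) {
        d <- rhs_delta_raw(y[1:n], y[(n + 1):(2 * n)], rates)
        c(d$df1, d$df2)
      }
    },
    {
      stopifnot(inherits(kernel, "separable_kernel"))
      stopifnot_same_grid(grid, kernel$grid)
      function(t, y) {
        d <- rhs_separable_raw(y[1:n], y[(n + 1):(2 * n)], kernel, rates, grid, mode)
        c(d$df1, d$df2)
      }
    }
  )

  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end - dt / 2) times <- c(times, t_end)
  states <- rk4_march(deriv, c(f1_0$values, f2_0$values), times)

  structure(
    list(times = f1_0$time + times,
         f1 = t(states[, 1:n, drop = FALSE]),
         f2 = t(states[, (n + 1):(2 * n), drop = FALSE]),
         grid = grid, mode = mode, rates = rates, dt = dt),
    class = "kinetic_trajectory"
  )
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat(sprintf("<kinetic_trajectory> mode %s: %d nodes x %d times, t in [%g, %g]\n",
              x$mode, x$grid$n_nodes, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one population's state from a trajectory
#'
#' @param traj A `kinetic_trajectory`.
#' @param population 1 or 2.
#' @param t Requested time; the nearest recorded time is returned.
#' @return A `density_state` (flagged un-normalised: the reduced dynamics do
#'   not conserve mass in general).
#' @export
state_at <- function(traj, population = 1L, t) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  idx <- which.min(abs(traj$times - t))
  vals <- if (population == 1L) traj$f1[, idx] else traj$f2[, idx]
  density_state(traj$grid, vals, time = traj$times[idx], normalized = FALSE)
}

#' Mass drift of a kinetic trajectory
#'
#' Quadrature mass of each population along the run, relative to its initial
#' value. The reduced separable and delta dynamics substitute the unit-mass
#' constraint into the loss term only, so they do not conserve mass in
#' general; this diagnostic makes the drift visible.
#'
#' @param traj A `kinetic_trajectory`.
#' @return A tibble with columns `t`, `mass1`, `mass2`, `drift1`, `drift2`.
#' @export
mass_drift <- function(traj) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  w <- traj$grid$weights
  m1 <- as.vector(crossprod(traj$f1, w))
  m2 <- as.vector(crossprod(traj$f2, w))
  tibble::tibble(t = traj$times, mass1 = m1, mass2 = m2,
                 drift1 = m1 - m1[1L], drift2 = m2 - m2[1L])
}

#' Analytic decay of the difference state
#'
#' Under Dirac-delta kernels with all four encounter rates equal to `eta`,
#' the difference f = f1 - f2 obeys df/dt = -2 eta f, so
#' f(t, u) = f(0, u) exp(-2 eta t). For the Gaussian reference profile this
#' gives f(t, u) = exp(-(u^2 + 2 eta t)) / sqrt(pi).
#'
#' @param d0 Initial `difference_state`.
#' @param eta Common encounter rate (>= 0).
#' @param t Elapsed time (>= 0).
#' @return A `difference_state` at time `d0$time + t`.
#' @export
analytic_difference <- function(d0, eta, t) {
  stopifnot(inherits(d0, "difference_state"))
  if (!is.numeric(eta) || eta < 0 || !is.numeric(t) || t < 0)
    stop("`eta` and `t` must be nonnegative.", call. = FALSE)
  new_difference_state(d0$grid, d0$values * exp(-2 * eta * t),
                       time = d0$time + t)
}

#' Split a difference profile into two nonnegative densities
#'
#' The model pins down only the initial difference f1 - f2, not the split.
#' This helper returns `f1 = base + d0` and `f2 = base` for a positive base
#' density; under equal-rate delta dynamics the evolved difference is
#' insensitive to the choice of base.
#'
#' @param d0 A `difference_state` with nonnegative values.
#' @param base A positive `density_state` on the same grid (default: a
#'   seeded random density).
#' @return List with `f1` and `f2` (`f1` is flagged un-normalised).
#' @export
split_difference <- function(d0, base = random_density(d0$grid, seed = 7L)) {
  stopifnot(inherits(d0, "difference_state"), inherits(base, "density_state"))
  stopifnot_same_grid(d0$grid, base$grid)
  if (any(d0$values + base$values < 0))
    stop("split would produce a negative density; choose a larger base.",
         call. = FALSE)
  list(f1 = density_state(d0$grid, base$values + d0$values, time = d0$time,
                          normalized = FALSE),
       f2 = density_state(d0$grid, base$values, time = d0$time,
                          normalized = FALSE))
}

#' @export
as_tibble.kinetic_trajectory <- function(x, ...) {
  nt <- length(x$times)
  tibble::tibble(
    t = rep(x$times, each = x$grid$n_nodes),
    u = rep(x$grid$nodes, times = nt),
    f1 = as.vector(x$f1),
    f2 = as.vector(x$f2)
  )
}

#' Write a kinetic trajectory to CSV (+ JSON sidecar)
#'
#' One row per (time, node) with columns `t`, `u`, `f1`, `f2`; run metadata
#' (mode, rates, dt) goes to `<path>.json`.
#'
#' @param traj A `kinetic_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  meta <- list(mode = traj$mode, rates = traj$rates$eta, dt = traj$dt,
               grid = list(lower = traj$grid$lower, upper = traj$grid$upper,
                           n_nodes = traj$grid$n_nodes))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
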