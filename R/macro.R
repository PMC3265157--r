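#' Lotka-Volterra parameters
#'
#' The four rate constants of the predator-prey system: `a` prey (tumour)
#' growth, `b` predation, `c` predator (immune) conversion, `d` predator
#' death. All strictly positive, per unit time.
#'
#' @param a,b,c,d Strictly positive finite rates.
#' @return An object of class `lv_params`.
#' @examples
#' lv_params(a = 2, b = 1, c = 1, d = 3)
#' @export
lv_params <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single strictly positive finite number.", nm),
           call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d), class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat(sprintf("<lv_params> a = %g, b = %g, c = %g, d = %g\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Classical Lotka-Volterra vector field
#'
#' `dx/dt = a x - b x y`, `dy/dt = c x y - d y`. Both axes are invariant
#' manifolds, so trajectories from positive initial data stay positive.
#'
#' @param x,y Population sizes (prey/tumour and predator/immune).
#' @param params An [lv_params()].
#' @return Numeric vector `c(dx, dy)`.
#' @export
classical_lv_rhs <- function(x, y, params) {
  stopifnot(inherits(params, "lv_params"))
  c(params$a * x - params$b * x * y,
    params$c * x * y - params$d * y)
}

#' Hybrid (mu-modified) Lotka-Volterra vector field
#'
#' The hiding-learning functional scales only the predation term of the prey
#' equation: `dx/dt = a x - mu b x y`, `dy/dt = c x y - d y`. With `mu = 1`
#' (complete learning) this is the classical field; with `mu = 0` the tumour
#' proliferates unhindered.
#'
#' @param x,y Population sizes.
#' @param params An [lv_params()].
#' @param mu_t Learning-functional value at the current time, in `[0, 1]`.
#' @return Numeric vector `c(dx, dy)`.
#' @export
hybrid_lv_rhs <- function(x, y, params, mu_t) {
  stopifnot(inherits(params, "lv_params"))
  if (!is.numeric(mu_t) || length(mu_t) != 1L || !is.finite(mu_t) ||
      mu_t < 0 || mu_t > 1)
    stop("`mu_t` must be a single number in [0, 1].", call. = FALSE)
  c(params$a * x - mu_t * params$b * x * y,
    params$c * x * y - params$d * y)
}

#' Nonzero equilibrium of the classical system
#'
#' The interior fixed point `(d/c, a/b)`. With `method = "numeric"` the
#' simultaneous zeros of the vector field are instead located by
#' root-finding from a positive start (`pracma::fsolve`, polished by Newton
#' steps with the analytic Jacobian), which serves as an independent check on
#' the closed form.
#'
#' @param params An [lv_params()].
#' @param method `"closed_form"` (default) or `"numeric"`.
#' @param start Starting point for the numeric search.
#' @return A one-row tibble with columns `x`, `y`, `method`.
#' @examples
#' equilibrium_classical(lv_params(2, 1, 1, 3)) # x = 3, y = 2
#' @export
equilibrium_classical <- function(params, method = c("closed_form", "numeric"),
                                  start = c(4, 1)) {
  stopifnot(inherits(params, "lv_params"))
  method <- match.arg(method)
  if (method == "closed_form") {
    xy <- c(params$d / params$c, params$a / params$b)
  } else {
    field <- function(p) classical_lv_rhs(p[1L], p[2L], params)
    sol <- pracma::fsolve(field, start, tol = 1e-12)
    xy <- sol$x
    # Newton polish with the analytic Jacobian to tighten past fsolve's stop
    for (it in 1:8) {
      J <- matrix(c(params$a - params$b * xy[2L], -params$b * xy[1L],
                    params$c * xy[2L], params$c * xy[1L] - params$d),
                  2, 2, byrow = TRUE)
      step <- solve(J, field(xy))
      xy <- xy - step
      if (max(abs(step)) < 1e-14) break
    }
  }
  tibble::tibble(x = xy[1L], y = xy[2L], method = method)
}

#' Instantaneous equilibrium of the hybrid system
#'
#' The time-dependent nullcline intersection `(d/c, a / (b mu(t)))` with the
#' closed-form learning functional. The x-coordinate is independent of time
#' and rate; the y-coordinate decreases monotonically to the classical value
#' `a/b` as learning completes. This is the instantaneous fixed point of the
#' frozen-time field, not an attractor statement for the nonautonomous
#' system.
#'
#' @param params An [lv_params()].
#' @param eta Common encounter rate (> 0 for a moving equilibrium).
#' @param t Time at which to evaluate.
#' @return A one-row tibble with columns `x`, `y`, `mu`.
#' @export
equilibrium_hybrid <- function(params, eta, t) {
  stopifnot(inherits(params, "lv_params"))
  mu <- mu_closed_form(t, eta)
  if (mu <= 0)
    stop("mu(t) = 0: the hybrid equilibrium is undefined.", call. = FALSE)
  tibble::tibble(x = params$d / params$c, y = params$a / (params$b * mu),
                 mu = mu)
}

#' First integral of the classical Lotka-Volterra flow
#'
#' `H(x, y) = c x - d log x + b y - a log y` is conserved along classical
#' trajectories; its level sets are the closed orbits around the interior
#' equilibrium, where H is stationary. Conservation of H along a numerical
#' trajectory verifies both the closed-orbit structure and the integrator.
#'
#' @param x,y Positive population sizes (vectorised).
#' @param params An [lv_params()].
#' @return H value(s).
#' @examples
#' lv_first_integral(4, 1, lv_params(2, 1, 1, 3)) # ~ 0.84111
#' @export
lv_first_integral <- function(x, y, params) {
  stopifnot(inherits(params, "lv_params"))
  if (any(x <= 0) || any(y <= 0))
    stop("H is defined for strictly positive populations only.", call. = FALSE)
  params$c * x - params$d * log(x) + params$b * y - params$a * log(y)
}

# --- mu sources -------------------------------------------------------------

#' @name mu_source
#' @title Sources of the time-dependent learning coefficient
#'
#' @description
#' A mu source is a function of time returning mu(t) in `[0, 1]`, tagged with
#' its provenance:
#'
#' * `mu_constant(value)` — frozen coefficient; `mu_constant(1)` recovers the
#'   classical system.
#' * `mu_closed_form_source(eta)` — the closed form
#'   `1 - exp(-4 eta t) / sqrt(2 pi)` of the equal-rate delta dynamics.
#' * `mu_from_trace(trace)` — linear interpolation of a recorded
#'   [mu_trace()] (constant extrapolation beyond its ends). Linear
#'   interpolation keeps the coupling error below the macroscopic
#'   integrator's own order for the step sizes used.
#'
#' @param value Constant mu in `[0, 1]`.
#' @param eta Common encounter rate, >= 0.
#' @param trace A `mu_trace`.
#' @return A function `f(t) -> mu`, class `mu_source`, with attribute `kind`.
NULL

new_mu_source <- function(f, kind, ...) {
  structure(f, class = "mu_source", kind = kind, meta = list(...))
}

#' @rdname mu_source
#' @export
mu_constant <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || value < 0 || value > 1)
    stop("constant mu must lie in [0, 1].", call. = FALSE)
  new_mu_source(function(t) rep(value, length(t)), kind = "constant",
                value = value)
}

#' @rdname mu_source
#' @export
mu_closed_form_source <- function(eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 0)
    stop("`eta` must be a single nonnegative rate.", call. = FALSE)
  new_mu_source(function(t) mu_closed_form(t, eta), kind = "closed_form",
                eta = eta)
}

#' @rdname mu_source
#' @export
mu_from_trace <- function(trace) {
  stopifnot(inherits(trace, "mu_trace"))
  f <- stats::approxfun(trace$t, trace$mu, rule = 2)
  new_mu_source(f, kind = "kinetic", t_range = range(trace$t))
}

#' @export
print.mu_source <- function(x, ...) {
  cat(sprintf("<mu_source> kind: %s\n", attr(x, "kind")))
  invisible(x)
}

# --- macroscopic solver -----------------------------------------------------

#' Integrate the (hybrid) Lotka-Volterra system
#'
#' Fixed-step fourth-order Runge-Kutta on the mu-modified system, with mu
#' evaluated from the source at every internal stage time. The recorded `mu`
#' column is the value used at each step's start. `mu_constant(1)` reproduces
#' the classical system exactly.
#'
#' @param params An [lv_params()].
#' @param x0,y0 Nonnegative initial populations.
#' @param mu_source A [mu_constant()], [mu_closed_form_source()] or
#'   [mu_from_trace()].
#' @param t_end Final time (> 0). Default 40 covers several orbit periods at
#'   the reference parameter set.
#' @param dt Step size (> 0), default 1e-3.
#' @return A `hybrid_result`: tibble with columns `t`, `x`, `y`, `mu` and
#'   attributes `params`, `dt`, `mu_kind`.
#' @examples
#' p <- lv_params(2, 1, 1, 3)
#' res <- solve_macro(p, 4, 1, mu_constant(1), t_end = 5, dt = 0.01)
#' head(res)
#' @export
solve_macro <- function(params, x0, y0, mu_source = mu_constant(1),
                        t_end = 40, dt = 1e-3) {
  stopifnot(inherits(params, "lv_params"), inherits(mu_source, "mu_source"))
  if (!is.numeric(x0) || x0 < 0 || !is.numeric(y0) || y0 < 0)
    stop("initial populations must be nonnegative.", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0 || !is.numeric(t_end) || t_end <= 0)
    stop("`dt` and `t_end` must be positive.", call. = FALSE)

  deriv <- function(t, s) {
    mu <- mu_source(t)
    c(params$a * s[1L] - mu * params$b * s[1L] * s[2L],
      params$c * s[1L] * s[2L] - params$d * s[2L])
  }
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end - dt / 2) times <- c(times, t_end)
  states <- rk4_march(deriv, c(x0, y0), times)

  out <- tibble::tibble(t = times, x = states[, 1L], y = states[, 2L],
                        mu = mu_source(times))
  class(out) <- c("hybrid_result", class(out))
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  attr(out, "mu_kind") <- attr(mu_source, "kind")
  out
}

#' Write a macroscopic run to CSV (+ JSON sidecar)
#'
#' Columns `t`, `x`, `y`, `mu`; parameters and solver settings are echoed to
#' `<path>.json`.
#'
#' @param res A `hybrid_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_macro_csv <- function(res, path) {
  stopifnot(inherits(res, "hybrid_result"))
  readr::write_csv(tibble::as_tibble(res), path)
  p <- attr(res, "params")
  jsonlite::write_json(
    list(params = list(a = p$a, b = p$b, c = p$c, d = p$d),
         dt = attr(res, "dt"), mu_kind = attr(res, "mu_kind")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
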