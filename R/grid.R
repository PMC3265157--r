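#' Discretised activity domain with Simpson quadrature
#'
#' Builds a uniform grid on the truncated activity domain `[lower, upper]`
#' together with composite Simpson quadrature weights. The activity variable
#' `u` is the scalar microscopic state of an active particle (a cell);
#' distributions over `u` characterise each population. The default domain
#' `[-6, 6]` truncates the real line where the Gaussian reference profile
#' `exp(-u^2)` has decayed below double-precision noise (< 3e-16 at |u| = 6).
#'
#' @param lower,upper Finite domain endpoints, `lower < upper`.
#' @param n_nodes Odd integer >= 3 (composite Simpson needs an even number of
#'   panels, i.e. an odd node count).
#' @return An object of class `activity_grid`: a list with elements `lower`,
#'   `upper`, `n_nodes`, `nodes` (uniformly spaced, strictly increasing) and
#'   `weights` (positive, summing to `upper - lower`).
#' @examples
#' g <- activity_grid(-1, 1, 3)
#' g$weights # 1/3, 4/3, 1/3
#' @export
activity_grid <- function(lower = -6, upper = 6, n_nodes = 241L) {
  if (!is.numeric(lower) || length(lower) != 1L || !is.finite(lower))
    stop("`lower` must be a single finite number.", call. = FALSE)
  if (!is.numeric(upper) || length(upper) != 1L || !is.finite(upper))
    stop("`upper` must be a single finite number.", call. = FALSE)
  if (lower >= upper)
    stop("`lower` must be strictly less than `upper`.", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 3L)
    stop("`n_nodes` must be an integer >= 3.", call. = FALSE)
  if (n_nodes %% 2L == 0L)
    stop("`n_nodes` must be odd (composite Simpson rule).", call. = FALSE)

  h <- (upper - lower) / (n_nodes - 1L)
  nodes <- lower + h * (seq_len(n_nodes) - 1L)
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1L] <- 1
  w[n_nodes] <- 1
  weights <- w * h / 3

  structure(
    list(lower = lower, upper = upper, n_nodes = n_nodes,
         nodes = nodes, weights = weights, spacing = h),
    class = "activity_grid"
  )
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("<activity_grid> [%g, %g], %d nodes, spacing %g (Simpson)\n",
              x$lower, x$upper, x$n_nodes, x$spacing))
  invisible(x)
}

is_activity_grid <- function(x) inherits(x, "activity_grid")

same_grid <- function(g1, g2) {
  g1$n_nodes == g2$n_nodes &&
    isTRUE(all.equal(g1$lower, g2$lower)) &&
    isTRUE(all.equal(g1$upper, g2$upper))
}

stopifnot_same_grid <- function(g1, g2) {
  if (!same_grid(g1, g2))
    stop("states/kernels live on different activity grids.", call. = FALSE)
  invisible(TRUE)
}

#' Quadrature over the activity domain
#'
#' Approximates the integral of per-node `values` over the grid's domain with
#' the grid's composite Simpson weights. Exact (to roundoff) for polynomials
#' of degree <= 3; fourth-order accurate in general.
#'
#' @param grid An [activity_grid()].
#' @param values Numeric vector, one finite value per grid node.
#' @return The scalar quadrature approximation of the integral.
#' @examples
#' g <- activity_grid()
#' grid_integrate(g, exp(-g$nodes^2) / sqrt(pi)) # ~ 1
#' @export
grid_integrate <- function(grid, values) {
  if (!is_activity_grid(grid)) stop("`grid` must be an activity_grid.", call. = FALSE)
  if (length(values) != grid$n_nodes)
    stop(sprintf("`values` must have one entry per node (%d), got %d.",
                 grid$n_nodes, length(values)), call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must all be finite.", call. = FALSE)
  sum(grid$weights * values)
}

#' @export
as_tibble.activity_grid <- function(x, ...) {
  tibble::tibble(u = x$nodes, weight = x$weights)
}

grid_to_json <- function(grid) {
  jsonlite::toJSON(list(lower = grid$lower, upper = grid$upper,
                        n_nodes = grid$n_nodes), auto_unbox = TRUE)
}

grid_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  activity_grid(x$lower, x$upper, x$n_nodes)
}
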