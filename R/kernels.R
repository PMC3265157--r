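#' Encounter-rate matrix
#'
#' The 2x2 nonnegative matrix eta[i, j] of binary-interaction rates between
#' a candidate particle of population i and a field particle of population j
#' (per unit time).
#'
#' @param eta A single nonnegative number (recycled to all four entries) or a
#'   2x2 nonnegative matrix.
#' @return An object of class `encounter_rates` wrapping the 2x2 matrix.
#' @examples
#' encounter_rates(1 / 4)
#' @export
encounter_rates <- function(eta) {
  if (is.numeric(eta) && length(eta) == 1L) eta <- matrix(eta, 2, 2)
  eta <- as.matrix(eta)
  if (!all(dim(eta) == c(2L, 2L)))
    stop("`eta` must be a scalar or a 2x2 matrix.", call. = FALSE)
  if (!all(is.finite(eta)) || any(eta < 0))
    stop("encounter rates must be finite and nonnegative.", call. = FALSE)
  structure(list(eta = unname(eta)), class = "encounter_rates")
}

#' @export
print.encounter_rates <- function(x, ...) {
  cat("<encounter_rates>\n")
  print(x$eta)
  invisible(x)
}

all_rates_equal <- function(rates) {
  e <- rates$eta
  isTRUE(all.equal(max(e), min(e)))
}

# --- general tabulated kernel -----------------------------------------------

#' General tabulated transition kernel
#'
#' The transition density phi_ij(u_cand, u_field, u_out): the probability
#' density that a candidate particle of population i with activity `u_cand`,
#' after meeting a field particle of population j with activity `u_field`,
#' lands at activity `u_out`. Each component is stored as an
#' `n x n x n` array indexed `[u_cand, u_field, u_out]`; the last index is the
#' density direction and must integrate to 1 for every `(u_cand, u_field)`
#' pair, unless the component is flagged as exempt (components forced to zero
#' by a separable factorisation are exempt by construction).
#'
#' @param grid An [activity_grid()].
#' @param components A list with entries `phi11`, `phi12`, `phi21`, `phi22`;
#'   each either an `n x n x n` nonnegative array or `NULL` (identically
#'   zero).
#' @param skip_norm_check Character vector of component names exempt from the
#'   unit-normalisation check (e.g. the zero diagonal of a separable kernel).
#' @param tol Tolerance of the normalisation check at construction.
#' @return An object of class `transition_kernel`.
#' @seealso [separable_to_general()], [check_normalization()], [uniform_kernel()]
#' @export
transition_kernel <- function(grid, components, skip_norm_check = character(),
                              tol = 1e-6) {
  if (!is_activity_grid(grid)) stop("`grid` must be an activity_grid.", call. = FALSE)
  nm <- c("phi11", "phi12", "phi21", "phi22")
  if (!all(nm %in% names(components)))
    stop("`components` must contain phi11, phi12, phi21, phi22 (NULL allowed).",
         call. = FALSE)
  n <- grid$n_nodes
  for (cn in nm) {
    comp <- components[[cn]]
    if (is.null(comp)) next
    if (!is.array(comp) || !all(dim(comp) == c(n, n, n)))
      stop(sprintf("component %s must be an %d x %d x %d array.", cn, n, n, n),
           call. = FALSE)
    if (any(comp < 0)) stop(sprintf("component %s has negative entries.", cn),
                            call. = FALSE)
  }
  k <- structure(list(grid = grid, components = components[nm],
                      skip_norm_check = skip_norm_check),
                 class = "transition_kernel")
  rep_ <- check_normalization(k)
  if (rep_$worst_deviation > tol)
    stop(sprintf(
      "kernel component %s violates unit normalization (worst |int phi du - 1| = %.3g at u_cand index %d, u_field index %d).",
      rep_$component, rep_$worst_deviation, rep_$i_cand, rep_$i_field),
      call. = FALSE)
  k
}

#' @export
print.transition_kernel <- function(x, ...) {
  nz <- names(Filter(Negate(is.null), x$components))
  cat(sprintf("<transition_kernel> %d nodes; nonzero components: %s\n",
              x$grid$n_nodes, paste(nz, collapse = ", ")))
  invisible(x)
}

#' Uniform transition kernel
#'
#' All four components constant at `1 / (upper - lower)`: every interaction
#' redistributes the candidate uniformly over the activity domain. Exactly
#' normalised under the Simpson weights, so useful for mass-conservation
#' checks.
#'
#' @param grid An [activity_grid()].
#' @return A `transition_kernel`.
#' @export
uniform_kernel <- function(grid) {
  n <- grid$n_nodes
  val <- 1 / (grid$upper - grid$lower)
  comp <- array(val, dim = c(n, n, n))
  transition_kernel(grid, list(phi11 = comp, phi12 = comp,
                               phi21 = comp, phi22 = comp))
}

#' Worst normalisation deviation of a tabulated kernel
#'
#' For every component and every `(u_cand, u_field)` pair, computes the
#' quadrature of the kernel over the outgoing activity and reports the
#' largest absolute deviation from 1, with the offending component and node
#' indices. Components listed in the kernel's `skip_norm_check` flag (and
#' `NULL` components) are skipped.
#'
#' @param k A `transition_kernel`.
#' @return A one-row tibble with columns `worst_deviation`, `component`,
#'   `i_cand`, `i_field`.
#' @export
check_normalization <- function(k) {
  stopifnot(inherits(k, "transition_kernel"))
  n <- k$grid$n_nodes
  w <- k$grid$weights
  worst <- 0
  worst_comp <- NA_character_
  worst_ab <- c(NA_integer_, NA_integer_)
  for (cn in names(k$components)) {
    comp <- k$components[[cn]]
    if (is.null(comp) || cn %in% k$skip_norm_check) next
    # integrate out the last index: (n*n) x n matrix times weights
    mass <- matrix(matrix(comp, n * n, n) %*% w, n, n)
    dev <- abs(mass - 1)
    m <- max(dev)
    if (m > worst) {
      worst <- m
      worst_comp <- cn
      worst_ab <- which(dev == m, arr.ind = TRUE)[1L, ]
    }
  }
  tibble::tibble(worst_deviation = worst, component = worst_comp,
                 i_cand = as.integer(worst_ab[1L]),
                 i_field = as.integer(worst_ab[2L]))
}

# --- separable kernel -------------------------------------------------------

#' Separable transition kernel
#'
#' Factorised transition density phi_ij = psi_i(u_cand, u_out) *
#' xi_j(u_field, u_out) for i != j; the diagonal components vanish. Both
#' factors are strictly positive and the *product* satisfies the unit
#' normalisation: for every pair `(u_cand, u_field)` and each ordered cross
#' pair, the quadrature over `u_out` of `psi_i(u_cand, .) * xi_j(u_field, .)`
#' is 1 (the model constrains only the product's integral, so any
#' rescaling convention is absorbed into the factors jointly).
#'
#' @param grid An [activity_grid()].
#' @param psi List of two `n x n` matrices, `psi[[i]][a, k]` =
#'   psi_i(u_cand_a, u_out_k), strictly positive.
#' @param xi List of two `n x n` matrices, `xi[[j]][b, k]` =
#'   xi_j(u_field_b, u_out_k), strictly positive.
#' @param tol Tolerance of the product-normalisation check.
#' @return An object of class `separable_kernel`.
#' @seealso [make_separable_fixture()], [separable_to_general()]
#' @export
separable_kernel <- function(grid, psi, xi, tol = 1e-6) {
  if (!is_activity_grid(grid)) stop("`grid` must be an activity_grid.", call. = FALSE)
  n <- grid$n_nodes
  chk <- function(m, what) {
    if (!is.matrix(m) || !all(dim(m) == c(n, n)))
      stop(sprintf("%s must be an %d x %d matrix.", what, n, n), call. = FALSE)
    if (any(m <= 0)) stop(sprintf("%s must be strictly positive.", what), call. = FALSE)
  }
  chk(psi[[1]], "psi[[1]]"); chk(psi[[2]], "psi[[2]]")
  chk(xi[[1]], "xi[[1]]"); chk(xi[[2]], "xi[[2]]")
  w <- grid$weights
  for (pair in list(c(1L, 2L), c(2L, 1L))) {
    i <- pair[1L]; j <- pair[2L]
    # product mass for all (a, b): psi_i diag(w) t(xi_j)
    mass <- (psi[[i]] * rep(w, each = n)) %*% t(xi[[j]])
    dev <- max(abs(mass - 1))
    if (dev > tol)
      stop(sprintf(
        "separable product psi_%d * xi_%d violates unit normalization (worst deviation %.3g).",
        i, j, dev), call. = FALSE)
  }
  structure(list(grid = grid, psi = psi, xi = xi),
            class = "separable_kernel")
}

#' @export
print.separable_kernel <- function(x, ...) {
  cat(sprintf("<separable_kernel> %d nodes (cross components only)\n",
              x$grid$n_nodes))
  invisible(x)
}

#' Expand a separable kernel to a general tabulated kernel
#'
#' Builds the dense `n x n x n` cross components phi12 = psi1 * xi2 and
#' phi21 = psi2 * xi1; the diagonal components are identically zero (stored
#' as `NULL`) and flagged exempt from the unit-normalisation check, which the
#' factorisation forces.
#'
#' @param k A `separable_kernel`.
#' @return A `transition_kernel` with zero diagonal.
#' @export
separable_to_general <- function(k) {
  stopifnot(inherits(k, "separable_kernel"))
  n <- k$grid$n_nodes
  expand <- function(psi, xi) {
    # out[a, b, m] = psi[a, m] * xi[b, m]
    out <- array(0, dim = c(n, n, n))
    for (m in seq_len(n)) out[, , m] <- outer(psi[, m], xi[, m])
    out
  }
  transition_kernel(
    k$grid,
    list(phi11 = NULL,
         phi12 = expand(k$psi[[1]], k$xi[[2]]),
         phi21 = expand(k$psi[[2]], k$xi[[1]]),
         phi22 = NULL),
    skip_norm_check = c("phi11", "phi22")
  )
}

#' Seeded random separable kernel (test fixture)
#'
#' Constructs a smooth, strictly positive separable kernel satisfying the
#' product normalisation to solver precision. Each psi_i row (one per
#' candidate activity) is a convex mixture of `m` fixed Gaussian bump
#' densities in the outgoing activity, each pre-normalised under the grid's
#' quadrature; the mixture weights vary smoothly with the candidate activity.
#' Each xi_j row is `1 + beta_j(u_field) * v(u_out)` where `v` is a smooth
#' bump made discretely orthogonal (small linear solve) to every mixture
#' component, so the product quadrature equals 1 for every
#' `(u_cand, u_field)` pair while both factors genuinely depend on both
#' arguments. Deterministic per seed.
#'
#' @param grid An [activity_grid()].
#' @param seed Integer seed.
#' @param m Number of mixture components (>= 2).
#' @return A `separable_kernel`.
#' @export
make_separable_fixture <- function(grid, seed = 1L, m = 3L) {
  if (!is_activity_grid(grid)) stop("`grid` must be an activity_grid.", call. = FALSE)
  n <- grid$n_nodes
  w <- grid$weights
  u <- grid$nodes
  L <- grid$upper - grid$lower

  eval_with_seed(seed, {
    centers <- grid$lower + L * (seq_len(m) - 0.5) / m +
      stats::runif(m, -0.05, 0.05) * L
    sig <- L / (2.5 * m)
    rho <- sapply(centers, function(cc) exp(-((u - cc) / sig)^2))
    rho <- sweep(rho, 2L, colSums(rho * w), "/")      # n x m, quad-normalised

    # v: smooth bump, projected to be quadrature-orthogonal to every rho_r
    v_raw <- sin(2 * pi * (u - grid$lower) / L) * exp(-((u - mean(u)) / (L / 4))^2)
    G <- crossprod(rho, w * rho)                      # m x m Gram matrix
    coef <- solve(G, crossprod(rho, w * v_raw))
    v <- v_raw - as.vector(rho %*% coef)              # t(rho) %*% (w * v) = 0
    v <- v / max(abs(v))

    mix_weights <- function() {
      s <- (u - grid$lower) / L
      a <- sapply(seq_len(m), function(r)
        exp(stats::rnorm(1) * sin(pi * r * s) + stats::rnorm(1) * cos(pi * r * s)))
      a / rowSums(a)                                   # n x m, rows on simplex
    }
    psi <- lapply(1:2, function(i) mix_weights() %*% t(rho)) # [a, k]
    xi <- lapply(1:2, function(j) {
      beta <- 0.45 * tanh(stats::rnorm(1) + stats::rnorm(1) * u / L * 2)
      1 + outer(beta, v)                               # [b, k], > 0
    })
    separable_kernel(grid, psi = psi, xi = xi)
  })
}

#' Serialise a separable fixture descriptor to JSON
#'
#' Fixtures are reproducible from `(grid, seed, m)`, so only the descriptor
#' is stored, never the tables.
#'
#' @param grid An [activity_grid()].
#' @param seed Integer seed used by [make_separable_fixture()].
#' @param m Mixture size.
#' @return A JSON string.
#' @export
separable_fixture_descriptor <- function(grid, seed, m = 3L) {
  jsonlite::toJSON(list(family = "gaussian_mixture_separable",
                        lower = grid$lower, upper = grid$upper,
                        n_nodes = grid$n_nodes, seed = seed, m = m),
                   auto_unbox = TRUE)
}

#' Symbolic Dirac-delta kernel
#'
#' Marks the choice psi_i = delta(u - u_cand), xi_j = delta(u - u_field). The
#' delta is never discretised on the grid: this marker routes the kinetic
#' solver to the analytically reduced local equations, which a grid
#' representation could only approximate with resolution-dependent error.
#'
#' @return An object of class `delta_kernel`.
#' @export
delta_kernel <- function() structure(list(), class = "delta_kernel")

#' @export
print.delta_kernel <- function(x, ...) {
  cat("<delta_kernel> symbolic Dirac-delta transition density\n")
  invisible(x)
}
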