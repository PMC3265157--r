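test_that("Simpson grid has the textbook weights and partitions the domain", {
  g <- activity_grid(-1, 1, 3)
  expect_equal(g$weights, c(1, 4, 1) / 3)

  g2 <- activity_grid(-6, 6, 241)
  expect_true(all(g2$weights > 0))
  expect_equal(sum(g2$weights), 12, tolerance = 1e-12)
  expect_equal(grid_integrate(g2, rep(1, 241)), 12, tolerance = 1e-12)
  expect_true(all(diff(g2$nodes) > 0))
  expect_equal(diff(range(diff(g2$nodes))), 0, tolerance = 1e-12)
})

test_that("grid construction rejects malformed inputs with a named message", {
  expect_error(activity_grid(-1, 1, 4), "odd")
  expect_error(activity_grid(1, -1, 5), "lower")
  expect_error(activity_grid(-Inf, 1, 5), "lower")
  expect_error(activity_grid(-1, 1, 1), "n_nodes")
})

test_that("quadrature is exact for cubics on any valid grid", {
  set.seed(42)
  for (rep in 1:10) {
    lo <- runif(1, -5, 0)
    hi <- lo + runif(1, 1, 8)
    n <- 2 * sample(1:40, 1) + 1
    g <- activity_grid(lo, hi, n)
    cf <- rnorm(4)
    vals <- cf[1] + cf[2] * g$nodes + cf[3] * g$nodes^2 + cf[4] * g$nodes^3
    exact <- cf[1] * (hi - lo) + cf[2] * (hi^2 - lo^2) / 2 +
      cf[3] * (hi^3 - lo^3) / 3 + cf[4] * (hi^4 - lo^4) / 4
    expect_equal(grid_integrate(g, vals), exact,
                 tolerance = 1e-12 * max(1, abs(exact)))
  }
})

test_that("quadrature converges at fourth order on a generic smooth integrand", {
  # cos has nonzero odd derivatives at the endpoints, so the O(h^4) term
  # dominates (unlike rapidly decaying integrands, which superconverge)
  err <- function(n) {
    g <- activity_grid(-6, 6, n)
    abs(grid_integrate(g, cos(g$nodes)) - 2 * sin(6))
  }
  ratio <- err(31) / err(61)
  expect_gt(ratio, 12)
  expect_lt(ratio, 22)
})

test_that("Gaussian integrals on the default grid hit their closed forms", {
  g <- activity_grid()
  expect_equal(grid_integrate(g, exp(-g$nodes^2) / sqrt(pi)), 1,
               tolerance = 1e-10)
  expect_equal(grid_integrate(g, exp(-2 * g$nodes^2) / pi), 1 / sqrt(2 * pi),
               tolerance = 1e-8)
  expect_equal(grid_integrate(g, rep(0, g$n_nodes)), 0)
  expect_error(grid_integrate(g, rep(1, 10)), "per node")
})

test_that("gaussian_profile is the even unit-mass reference difference", {
  g <- activity_grid()
  d0 <- gaussian_profile(g)
  i0 <- which(abs(g$nodes) < 1e-12)
  expect_equal(d0$values[i0], 1 / sqrt(pi), tolerance = 1e-12)
  expect_equal(d0$values, rev(d0$values)) # even in u
  expect_equal(grid_integrate(g, d0$values), 1, tolerance = 1e-10)
  expect_equal(d0$time, 0)
})

test_that("random_density is a deterministic, strictly positive unit-mass fixture", {
  g <- small_grid()
  f_a <- random_density(g, seed = 11)
  f_b <- random_density(g, seed = 11)
  f_c <- random_density(g, seed = 12)
  expect_identical(f_a$values, f_b$values)
  expect_true(all(f_a$values > 0))
  expect_equal(grid_integrate(g, f_a$values), 1, tolerance = 1e-12)
  l2 <- sqrt(grid_integrate(g, (f_a$values - f_c$values)^2))
  expect_gt(l2, 0)
})

test_that("density validation enforces mass and nonnegativity, warns above 1", {
  g <- small_grid()
  expect_error(density_state(g, rep(1, g$n_nodes)), "mass")
  expect_error(density_state(g, -normal_values(g) / 1, normalized = TRUE),
               "nonnegative")
  # narrow density legitimately exceeds 1 pointwise: warning, not error
  vals <- normal_values(g, 0, 0.25)
  vals <- vals / grid_integrate(g, vals)
  expect_warning(density_state(g, vals), "exceeds 1")
  # renormalize fixes an off-mass state explicitly
  f <- renormalize(density_state(g, 2 * normal_values(g), normalized = FALSE))
  expect_equal(grid_integrate(g, f$values), 1, tolerance = 1e-12)
})

test_that("difference_state subtracts pointwise on a shared grid", {
  g <- small_grid()
  f1 <- random_density(g, 1)
  f2 <- random_density(g, 2)
  d <- difference_state(f1, f2)
  expect_equal(d$values, f1$values - f2$values)
  g2 <- small_grid(61)
  expect_error(difference_state(f1, random_density(g2, 1)), "grid")
})

test_that("states round-trip through tidy CSV", {
  g <- small_grid()
  f <- random_density(g, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_csv(f, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$u, g$nodes)
  expect_equal(back$value, f$values)
})
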