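test_that("delta right-hand side matches direct substitution", {
  g <- small_grid(21)
  n <- g$n_nodes
  f1 <- density_state(g, rep(0.5, n), normalized = FALSE)
  f2 <- density_state(g, rep(0.25, n), normalized = FALSE)
  d <- rhs_delta(f1, f2, encounter_rates(1))
  expect_equal(unique(d$df1), 0.125 - 1.0) # eta f1 f2 - 2 eta f1
  expect_equal(unique(d$df2), 0.125 - 0.5)
})

test_that("equal distributions and equal rates give symmetric dynamics", {
  g <- small_grid()
  f <- random_density(g, 3)
  d <- rhs_delta(f, f, encounter_rates(0.7))
  expect_equal(d$df1, d$df2)
})

test_that("the difference decays linearly at rate 2 eta under equal rates", {
  g <- small_grid()
  f1 <- random_density(g, 1)
  f2 <- random_density(g, 2)
  eta <- 0.4
  d <- rhs_delta(f1, f2, encounter_rates(eta))
  expect_equal(d$df1 - d$df2, -2 * eta * (f1$values - f2$values),
               tolerance = 1e-12)
})

test_that("separable loss reduces to a constant coefficient when gain vanishes", {
  g <- small_grid(31)
  k <- make_separable_fixture(g, seed = 1)
  f1 <- random_density(g, 1)
  f0 <- density_state(g, rep(0, g$n_nodes), normalized = FALSE)
  r <- encounter_rates(matrix(c(0.3, 0.5, 0.2, 0.7), 2, 2, byrow = TRUE))
  d <- rhs_separable(f1, f0, k, r, mode = "separable_reduced")
  expect_equal(d$df1, -(0.3 + 0.5) * f1$values, tolerance = 1e-12)
})

test_that("full and reduced separable modes agree on unit-mass states", {
  g <- small_grid(31)
  k <- make_separable_fixture(g, seed = 2)
  f1 <- random_density(g, 4)
  f2 <- random_density(g, 5)
  r <- encounter_rates(matrix(c(0.3, 0.5, 0.2, 0.7), 2, 2, byrow = TRUE))
  dfull <- rhs_separable(f1, f2, k, r, mode = "separable_full")
  dred <- rhs_separable(f1, f2, k, r, mode = "separable_reduced")
  expect_equal(dfull$df1, dred$df1, tolerance = 1e-10)
  expect_equal(dfull$df2, dred$df2, tolerance = 1e-10)
  # off unit mass they must differ
  f1_off <- density_state(g, 2 * f1$values, normalized = FALSE)
  expect_gt(max(abs(rhs_separable(f1_off, f2, k, r, "separable_full")$df1 -
                    rhs_separable(f1_off, f2, k, r, "separable_reduced")$df1)),
            1e-3)
})

test_that("general rhs on the expanded kernel reproduces the separable rhs", {
  g <- small_grid(31)
  r <- encounter_rates(matrix(c(0.1, 0.9, 0.4, 0.2), 2, 2, byrow = TRUE))
  for (seed in 1:3) {
    k <- make_separable_fixture(g, seed = seed)
    kg <- separable_to_general(k)
    f1 <- random_density(g, seed + 10)
    f2 <- random_density(g, seed + 20)
    ds <- rhs_separable(f1, f2, k, r, mode = "separable_full")
    dg <- rhs_general(f1, f2, kg, r)
    expect_lt(max(abs(ds$df1 - dg$df1)), 1e-8)
    expect_lt(max(abs(ds$df2 - dg$df2)), 1e-8)
  }
})

test_that("general rhs with a normalized kernel conserves mass instantaneously", {
  g <- small_grid(21)
  k <- uniform_kernel(g)
  f1 <- random_density(g, 1)
  f2 <- random_density(g, 2)
  d <- rhs_general(f1, f2, k, encounter_rates(1))
  expect_lt(abs(grid_integrate(g, d$df1)), 1e-10)
  expect_lt(abs(grid_integrate(g, d$df2)), 1e-10)
})

test_that("zero states yield a zero trajectory", {
  g <- small_grid(21)
  f0 <- density_state(g, rep(0, g$n_nodes), normalized = FALSE)
  traj <- evolve(f0, f0, mode = "delta_reduced", rates = encounter_rates(1),
                 t_end = 1, dt = 0.1)
  expect_true(all(traj$f1 == 0))
  expect_true(all(traj$f2 == 0))
})

test_that("delta-mode evolution reproduces the analytic decay of the difference", {
  g <- activity_grid()
  sp <- split_difference(gaussian_profile(g))
  traj <- evolve(sp$f1, sp$f2, mode = "delta_reduced",
                 rates = encounter_rates(1 / 4), t_end = 2, dt = 0.01)
  last <- length(traj$times)
  expect_equal(traj$times[last], 2)
  num <- traj$f1[, last] - traj$f2[, last]
  ana <- analytic_difference(gaussian_profile(g), 1 / 4, 2)$values
  expect_lt(max(abs(num - ana)), 1e-6)
})

test_that("the integrator error decays at fourth order in the step size", {
  g <- small_grid()
  sp <- split_difference(gaussian_profile(g))
  sup_err <- function(dt) {
    traj <- evolve(sp$f1, sp$f2, mode = "delta_reduced",
                   rates = encounter_rates(1 / 4), t_end = 2, dt = dt)
    num <- traj$f1[, ncol(traj$f1)] - traj$f2[, ncol(traj$f2)]
    max(abs(num - analytic_difference(gaussian_profile(g), 1 / 4, 2)$values))
  }
  ratio <- sup_err(0.1) / sup_err(0.05)
  expect_gt(ratio, 10)
  expect_lt(ratio, 25)
})

test_that("the evolved difference is insensitive to the split of the initial data", {
  g <- small_grid()
  d0 <- gaussian_profile(g)
  diff_after <- function(base_seed) {
    sp <- split_difference(d0, random_density(g, base_seed))
    traj <- evolve(sp$f1, sp$f2, mode = "delta_reduced",
                   rates = encounter_rates(1 / 4), t_end = 1, dt = 0.02)
    traj$f1[, ncol(traj$f1)] - traj$f2[, ncol(traj$f2)]
  }
  expect_equal(diff_after(7), diff_after(23), tolerance = 1e-12)
})

test_that("delta-mode evolution preserves positivity at a stable step size", {
  g <- small_grid()
  f1 <- random_density(g, 1)
  f2 <- random_density(g, 2)
  traj <- evolve(f1, f2, mode = "delta_reduced", rates = encounter_rates(0.5),
                 t_end = 3, dt = 0.05)
  expect_true(all(traj$f1 >= 0))
  expect_true(all(traj$f2 >= 0))
})

test_that("analytic_difference scales the profile and advances time", {
  g <- small_grid()
  d0 <- gaussian_profile(g)
  expect_equal(analytic_difference(d0, 0.7, 0)$values, d0$values)
  dt2 <- analytic_difference(d0, 1 / 4, 2)
  expect_equal(dt2$values, d0$values * exp(-1), tolerance = 1e-12)
  expect_equal(dt2$values, exp(-(g$nodes^2 + 2 * (1 / 4) * 2)) / sqrt(pi),
               tolerance = 1e-12)
  expect_equal(dt2$time, 2)
})

test_that("reduced dynamics report, rather than hide, mass drift", {
  g <- small_grid(31)
  k <- make_separable_fixture(g, seed = 3)
  f1 <- random_density(g, 1)
  f2 <- random_density(g, 2)
  r <- encounter_rates(0.5)
  traj <- evolve(f1, f2, mode = "separable_reduced", kernel = k, rates = r,
                 t_end = 2, dt = 0.02)
  md <- mass_drift(traj)
  expect_equal(md$mass1[1], 1, tolerance = 1e-10)
  # the reduced loss uses the unit-mass substitution, so mass is not conserved
  expect_gt(max(abs(c(md$drift1, md$drift2))), 1e-6)
})

test_that("evolution aborts with the failure time on blow-up", {
  g <- small_grid(11)
  big <- density_state(g, rep(700, g$n_nodes), normalized = FALSE)
  expect_error(
    evolve(big, big, mode = "delta_reduced", rates = encounter_rates(50),
           t_end = 10, dt = 0.5),
    "non-finite at t")
})

test_that("trajectories export one tidy row per time and node", {
  g <- small_grid(11)
  f1 <- random_density(g, 1)
  f2 <- random_density(g, 2)
  traj <- evolve(f1, f2, mode = "delta_reduced", rates = encounter_rates(1),
                 t_end = 0.2, dt = 0.1)
  tb <- tibble::as_tibble(traj)
  expect_equal(nrow(tb), length(traj$times) * g$n_nodes)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  expect_true(file.exists(path))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$mode, "delta_reduced")
  long <- tidy(traj)
  expect_setequal(unique(long$population), c("tumour", "immune"))
  expect_equal(glance(traj)$n_times, length(traj$times))
})
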