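ref_params <- lv_params(a = 2, b = 1, c = 1, d = 3)

test_that("classical vector field vanishes at (d/c, a/b) and on the axes", {
  expect_equal(classical_lv_rhs(3, 2, ref_params), c(0, 0))
  expect_equal(classical_lv_rhs(4, 1, ref_params), c(4, 1)) # (8-4, 4-3)
  expect_equal(classical_lv_rhs(0, 5, ref_params)[1], 0)
  expect_equal(classical_lv_rhs(5, 0, ref_params)[2], 0)
})

test_that("hybrid field reduces to classical at mu = 1 and to pure growth at mu = 0", {
  expect_equal(hybrid_lv_rhs(4, 1, ref_params, 1),
               classical_lv_rhs(4, 1, ref_params))
  expect_equal(hybrid_lv_rhs(4, 1, ref_params, 0)[1], 2 * 4)
  mu0 <- mu_closed_form(0, 1 / 4)
  expect_equal(hybrid_lv_rhs(4, 1, ref_params, mu0)[1], 8 - mu0 * 4)
  expect_equal(hybrid_lv_rhs(4, 1, ref_params, mu0)[1], 5.5957691,
               tolerance = 1e-7)
  expect_error(hybrid_lv_rhs(4, 1, ref_params, 1.5), "\\[0, 1\\]")
})

test_that("lv_params rejects nonpositive rates by name", {
  expect_error(lv_params(0, 1, 1, 1), "`a`")
  expect_error(lv_params(1, 1, 1, -2), "`d`")
})

test_that("closed-form and root-found equilibria agree", {
  eq <- equilibrium_classical(ref_params)
  expect_equal(c(eq$x, eq$y), c(3, 2))
  eq_same <- equilibrium_classical(lv_params(1.3, 1.3, 1.3, 1.3))
  expect_equal(c(eq_same$x, eq_same$y), c(1, 1))
  eq_num <- equilibrium_classical(ref_params, method = "numeric", start = c(4, 1))
  expect_equal(eq_num$x, 3, tolerance = 1e-10)
  expect_equal(eq_num$y, 2, tolerance = 1e-10)
})

test_that("hybrid equilibrium has fixed x and y decreasing to a/b", {
  eq0 <- equilibrium_hybrid(ref_params, eta = 1 / 4, t = 0)
  expect_equal(eq0$x, 3)
  expect_equal(eq0$y, 2 / (1 - 1 / sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(eq0$y, 3.3274675, tolerance = 1e-7)
  ts <- seq(0, 10, by = 0.5)
  ys <- vapply(ts, function(t) equilibrium_hybrid(ref_params, 1 / 4, t)$y,
               numeric(1))
  expect_true(all(diff(ys) < 0))            # monotone approach from above
  expect_true(all(ys > 2))
  expect_equal(equilibrium_hybrid(ref_params, 1 / 4, 100)$y, 2,
               tolerance = 1e-10)
  xs <- vapply(ts, function(t) equilibrium_hybrid(ref_params, 1 / 4, t)$x,
               numeric(1))
  expect_equal(unique(xs), 3)
})

test_that("the first integral is stationary at equilibrium and valued as expected", {
  p <- ref_params
  expect_equal(lv_first_integral(4, 1, p), 4 - 3 * log(4) + 1, tolerance = 1e-12)
  expect_equal(lv_first_integral(4, 1, p), 0.8411169, tolerance = 1e-7)
  # gradient components c - d/x and b - a/y vanish at (d/c, a/b)
  expect_equal(p$c - p$d / 3, 0)
  expect_equal(p$b - p$a / 2, 0)
  expect_error(lv_first_integral(-1, 1, p), "positive")
})

test_that("classical runs conserve H and converge at fourth order in dt", {
  drift <- function(dt) {
    run <- solve_macro(ref_params, 4, 1, mu_constant(1), t_end = 10, dt = dt)
    H <- lv_first_integral(run$x, run$y, ref_params)
    max(abs(H - H[1]))
  }
  expect_lt(drift(1e-2), 1e-4)
  ratio <- drift(0.04) / drift(0.02)
  expect_gt(ratio, 10)
  expect_lt(ratio, 25)
})

test_that("macro solutions from positive data stay positive", {
  for (start in list(c(4, 1), c(0.1, 9), c(0.5, 0.5))) {
    run <- solve_macro(ref_params, start[1], start[2],
                       mu_closed_form_source(1 / 4), t_end = 40, dt = 1e-2)
    expect_true(all(run$x > 0))
    expect_true(all(run$y > 0))
  }
})

test_that("a constant-1 mu source reproduces an independent classical solver", {
  skip_if_not_installed("deSolve")
  run <- solve_macro(ref_params, 4, 1, mu_constant(1), t_end = 10, dt = 1e-3)
  ref <- deSolve::ode(
    y = c(x = 4, y = 1), times = seq(0, 10, by = 0.1),
    func = function(t, s, p) list(classical_lv_rhs(s[1], s[2], ref_params)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  at <- match(round(ref[, "time"], 9), round(run$t, 9))
  expect_lt(max(abs(run$x[at] - ref[, "x"])), 1e-6)
  expect_lt(max(abs(run$y[at] - ref[, "y"])), 1e-6)
})

test_that("hybrid runs approach a conserved orbit as learning completes", {
  run <- solve_macro(ref_params, 4, 1, mu_closed_form_source(1 / 4),
                     t_end = 40, dt = 1e-3)
  H <- lv_first_integral(run$x, run$y, ref_params)
  windows <- split(H, cut(run$t, breaks = c(0, 20, 30, 40),
                          include.lowest = TRUE))
  spans <- vapply(windows, function(h) diff(range(h)), numeric(1))
  expect_true(all(diff(spans) < 0)) # successive windows ever closer to a level set
})

test_that("a kinetic mu source matches the closed form it discretises", {
  g <- activity_grid()
  sp <- split_difference(gaussian_profile(g))
  traj <- evolve(sp$f1, sp$f2, mode = "delta_reduced",
                 rates = encounter_rates(1 / 4), t_end = 10, dt = 0.01)
  run_kin <- solve_macro(ref_params, 4, 1, mu_from_trace(mu_trace(traj)),
                         t_end = 10, dt = 0.01)
  run_cf <- solve_macro(ref_params, 4, 1, mu_closed_form_source(1 / 4),
                        t_end = 10, dt = 0.01)
  expect_lt(max(abs(run_kin$x - run_cf$x)), 1e-4)
  expect_lt(max(abs(run_kin$y - run_cf$y)), 1e-4)
})

test_that("macro results carry tidy/glance/export machinery", {
  run <- solve_macro(ref_params, 4, 1, mu_constant(1), t_end = 1, dt = 0.01)
  td <- tidy(run)
  expect_named(td, c("t", "x", "y", "mu"))
  gl <- glance(run)
  expect_equal(gl$mu_kind, "constant")
  expect_lt(gl$H_drift, 1e-8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_macro_csv(run, path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$params$a, 2)
})
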