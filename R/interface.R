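#' @name run_config
#' @title Configuration-driven runs
#'
#' @description
#' A run configuration is a single YAML (or JSON) document with sections:
#'
#' * `grid`: `lower`, `upper`, `n_nodes` (defaults -6, 6, 241).
#' * `kinetic` (optional): `mode` (`general`, `separable_full`,
#'   `separable_reduced`, `delta_reduced`), `eta` (scalar rate, or `rates` as
#'   a 2x2 matrix), `dt`, `t_end`, `kernel` (`uniform` or
#'   `separable_fixture`; ignored for `delta_reduced`), `kernel_seed`, and
#'   `initial`: either `type: gaussian_split` with `base_seed` (split of the
#'   Gaussian reference difference over a seeded base density) or
#'   `type: random` with `f1_seed`, `f2_seed`.
#' * `mu`: `source` one of `constant` (+ `value`), `closed_form` (+ `eta`),
#'   `kinetic` (trace computed from the kinetic run, which must be present).
#' * `macro`: `a`, `b`, `c`, `d`, `x0`, `y0`, `dt` (default 1e-3), `t_end`
#'   (default 40).
#' * `seed`: integer, required whenever any seeded fixture is requested.
#'
#' Outputs (written atomically into `out_dir`: staged in a temporary
#' directory, moved only on success): `macro.csv` + `macro.csv.json`,
#' `mu_trace.csv`, and for kinetic runs `kinetic.csv` + `kinetic.csv.json`;
#' `run.json` echoes the config and records normalisation drift and any mu
#' clamping events.
NULL

cfg_need <- function(cfg, key, section) {
  if (is.null(cfg[[key]]))
    stop(sprintf("config is missing required key \"%s\" in section \"%s\".",
                 key, section), call. = FALSE)
  cfg[[key]]
}

cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

build_kinetic_inputs <- function(kin, grid, seed) {
  rates <- if (!is.null(kin$rates)) {
    encounter_rates(matrix(unlist(kin$rates), 2, 2, byrow = TRUE))
  } else {
    encounter_rates(cfg_need(kin, "eta", "kinetic"))
  }
  init <- cfg_need(kin, "initial", "kinetic")
  type <- cfg_need(init, "type", "kinetic.initial")
  states <- switch(
    type,
    gaussian_split = {
      base <- random_density(grid, seed = cfg_get(init, "base_seed", seed))
      split_difference(gaussian_profile(grid), base)
    },
    random = list(
      f1 = random_density(grid, seed = cfg_need(init, "f1_seed", "kinetic.initial")),
      f2 = random_density(grid, seed = cfg_need(init, "f2_seed", "kinetic.initial"))
    ),
    stop(sprintf("unknown kinetic.initial type \"%s\".", type), call. = FALSE)
  )
  mode <- cfg_need(kin, "mode", "kinetic")
  kernel <- if (mode == "delta_reduced") {
    delta_kernel()
  } else if (mode == "general") {
    kname <- cfg_get(kin, "kernel", "uniform")
    if (kname == "uniform") uniform_kernel(grid)
    else separable_to_general(
      make_separable_fixture(grid, seed = cfg_get(kin, "kernel_seed", seed)))
  } else {
    make_separable_fixture(grid, seed = cfg_get(kin, "kernel_seed", seed))
  }
  list(rates = rates, states = states, mode = mode, kernel = kernel,
       dt = cfg_need(kin, "dt", "kinetic"),
       t_end = cfg_need(kin, "t_end", "kinetic"))
}

#' Execute a run configuration
#'
#' Parses and validates the configuration, executes the kinetic layer (if
#' requested), builds the learning-functional trace, integrates the
#' macroscopic system, and writes all outputs. Validation failures name the
#' offending key; no partial outputs are left behind on failure.
#'
#' @param path Path to a YAML/JSON config file (see [run_config]).
#' @param out_dir Output directory (created if needed). `NULL` skips writing.
#' @return The macroscopic `hybrid_result`, invisibly, with the kinetic
#'   trajectory (if any) in attribute `kinetic` and the mu trace in
#'   attribute `mu_trace`.
#' @export
run_from_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)

  gcfg <- cfg_get(cfg, "grid", list())
  grid <- activity_grid(cfg_get(gcfg, "lower", -6), cfg_get(gcfg, "upper", 6),
                        cfg_get(gcfg, "n_nodes", 241L))
  seed <- cfg_get(cfg, "seed", 1L)

  notes <- list()
  traj <- NULL
  if (!is.null(cfg$kinetic)) {
    kin <- build_kinetic_inputs(cfg$kinetic, grid, seed)
    traj <- evolve(kin$states$f1, kin$states$f2, mode = kin$mode,
                   kernel = kin$kernel, rates = kin$rates,
                   t_end = kin$t_end, dt = kin$dt)
    md <- mass_drift(traj)
    drift <- max(abs(c(md$drift1, md$drift2)))
    notes$mass_drift <- drift
    if (drift > 1e-8)
      message(sprintf("kinetic mass drift %.3g over the run (reduced dynamics do not conserve mass).",
                      drift))
  }

  mcfg <- cfg_need(cfg, "mu", "top level")
  msrc_kind <- cfg_need(mcfg, "source", "mu")
  clamped <- 0L
  mu_src <- switch(
    msrc_kind,
    constant = mu_constant(cfg_need(mcfg, "value", "mu")),
    closed_form = mu_closed_form_source(cfg_need(mcfg, "eta", "mu")),
    kinetic = {
      if (is.null(traj))
        stop("mu source \"kinetic\" requires a \"kinetic\" section.", call. = FALSE)
      tr <- withCallingHandlers(
        mu_trace(traj),
        warning = function(w) {
          clamped <<- clamped + 1L
          invokeRestart("muffleWarning")
        })
      mu_from_trace(tr)
    },
    stop(sprintf("unknown mu source \"%s\".", msrc_kind), call. = FALSE)
  )
  notes$mu_clamping_events <- clamped

  mac <- cfg_need(cfg, "macro", "top level")
  params <- lv_params(cfg_need(mac, "a", "macro"), cfg_need(mac, "b", "macro"),
                      cfg_need(mac, "c", "macro"), cfg_need(mac, "d", "macro"))
  res <- solve_macro(params,
                     cfg_need(mac, "x0", "macro"), cfg_need(mac, "y0", "macro"),
                     mu_source = mu_src,
                     t_end = cfg_get(mac, "t_end", 40),
                     dt = cfg_get(mac, "dt", 1e-3))

  trace <- new_mu_trace(res$t, res$mu, source = msrc_kind, clamped = clamped)

  if (!is.null(out_dir)) {
    stage <- file.path(tempfile("hybridlv_run_"))
    dir.create(stage, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)
    write_macro_csv(res, file.path(stage, "macro.csv"))
    write_mu_trace_csv(trace, file.path(stage, "mu_trace.csv"))
    if (!is.null(traj)) write_trajectory_csv(traj, file.path(stage, "kinetic.csv"))
    jsonlite::write_json(list(config = cfg, notes = notes),
                         file.path(stage, "run.json"),
                         auto_unbox = TRUE, digits = NA)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in list.files(stage, full.names = TRUE))
      file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
    unlink(stage, recursive = TRUE)
    ok <- TRUE
  }

  attr(res, "kinetic") <- traj
  attr(res, "mu_trace") <- trace
  invisible(res)
}

#' Path to a packaged example configuration
#'
#' Packaged configs: `"figure1"` (classical orbit, a = 2, b = c = 1, d = 3,
#' start (4, 1), mu constant 1), `"figure2a"` (same parameters, closed-form
#' mu with eta = 1/4, start (4, 1)), `"figure2b"` (start (0.1, 9)).
#'
#' @param name Config name (without extension).
#' @return Path to the installed YAML file.
#' @export
example_config <- function(name = c("figure1", "figure2a", "figure2b")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "hybridlv")
  if (path == "") stop("packaged config not found; is the package installed?",
                       call. = FALSE)
  path
}

#' Fast invariant self-check
#'
#' Runs the package's core numerical invariants at the given resolution and
#' step sizes and reports each check's status: Simpson quadrature order and
#' Gaussian mass, the quadrature-vs-closed-form identity for mu, the
#' analytic-decay oracle for the delta-mode RK4 solver, and first-integral
#' conservation of the classical Lotka-Volterra run. Coarsening the grid or
#' the steps makes the corresponding checks fail, which is itself a useful
#' diagnostic.
#'
#' @param n_nodes Grid resolution for the quadrature/mu/kinetic checks.
#' @param dt_kinetic Kinetic step size.
#' @param dt_macro Macroscopic step size.
#' @return A tibble with columns `check`, `value`, `tolerance`, `pass`.
#' @export
selfcheck <- function(n_nodes = 241L, dt_kinetic = 0.01, dt_macro = 1e-3) {
  g <- activity_grid(n_nodes = n_nodes)
  checks <- list()

  # quadrature: 4th-order on a generic smooth integrand (boundary-driven error)
  ord_err <- function(n) {
    gg <- activity_grid(n_nodes = n)
    abs(grid_integrate(gg, cos(gg$nodes)) - 2 * sin(6))
  }
  ratio <- ord_err(31L) / ord_err(61L)
  checks$quadrature_order <- list(value = ratio, tol = NA_real_,
                                  pass = ratio > 10 && ratio < 25)

  mass <- grid_integrate(g, gaussian_profile(g)$values)
  checks$gaussian_mass <- list(value = abs(mass - 1), tol = 1e-10,
                               pass = abs(mass - 1) < 1e-10)

  disc <- mu_consistency_check(gaussian_profile(g), eta = 1 / 4,
                               times = c(0, 1, 2, 4))
  checks$mu_identity <- list(value = disc, tol = 1e-8, pass = disc < 1e-8)

  sp <- split_difference(gaussian_profile(g))
  traj <- evolve(sp$f1, sp$f2, mode = "delta_reduced",
                 rates = encounter_rates(1 / 4), t_end = 2, dt = dt_kinetic)
  num <- traj$f1[, ncol(traj$f1)] - traj$f2[, ncol(traj$f2)]
  ana <- analytic_difference(gaussian_profile(g), 1 / 4, 2)$values
  sup <- max(abs(num - ana))
  checks$delta_oracle <- list(value = sup, tol = 1e-6, pass = sup < 1e-6)

  p <- lv_params(2, 1, 1, 3)
  run <- solve_macro(p, 4, 1, mu_constant(1), t_end = 20, dt = dt_macro)
  H <- lv_first_integral(run$x, run$y, p)
  hd <- max(abs(H - H[1L]))
  checks$h_conservation <- list(value = hd, tol = 1e-4, pass = hd < 1e-4)

  tibble::tibble(
    check = names(checks),
    value = vapply(checks, function(x) x$value, numeric(1)),
    tolerance = vapply(checks, function(x) x$tol, numeric(1)),
    pass = vapply(checks, function(x) x$pass, logical(1))
  )
}
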