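# hybridlv

Simulator for a hybrid two-scale model of tumour–immune competition. A
tumour population proliferates and *hides* by reshaping its biological
activity; the immune population must *learn* that activity before its
destructive capacity takes effect. The package couples:

- a **kinetic layer**: each population carries a probability density
  `f_i(t, u)` over a scalar activity `u`, evolving under binary-interaction
  transition kernels `φ_ij(u*, u°, u)` with encounter rates `η_ij` —
  supported in general tabulated, separable (`φ_ij = ψ_i ξ_j`, zero
  diagonal), and symbolic Dirac-delta form;
- a **hiding-learning functional** `μ(t) = 1 − ∫ (f1 − f2)² du ∈ [0, 1]`,
  which is 1 exactly when the immune distribution has reproduced the tumour
  one; and
- a **macroscopic layer**: a Lotka–Volterra system whose predation term is
  modulated by learning,

  ```
  dx/dt = a x − μ(t) b x y,   dy/dt = c x y − d y.
  ```

With all encounter rates equal to `η` and Dirac-delta kernels, the
difference `f = f1 − f2` decays as `f(0, u) e^(−2ηt)`; from the Gaussian
reference profile `f(0, u) = e^(−u²)/√π` this gives the closed form
`μ(t) = 1 − e^(−4ηt)/√(2π)`, which serves as the package's analytic oracle
throughout. The classical interior equilibrium `(d/c, a/b)` becomes the
moving nullcline intersection `(d/c, a/(b μ(t)))`, relaxing onto the
classical point as learning completes.

## Worked example

Evolve the reference Gaussian difference under equal-rate delta dynamics,
recover the encounter rate from the simulated decay, and run the hybrid
macroscopic system:

```r
library(hybridlv)

g    <- activity_grid()                       # [-6, 6], 241 Simpson nodes
sp   <- split_difference(gaussian_profile(g)) # f1 - f2 = Gaussian reference
traj <- evolve(sp$f1, sp$f2, mode = "delta_reduced",
               rates = encounter_rates(1/4), t_end = 4, dt = 0.01)
fit_learning_rate(traj)
#> # A tibble: 1 × 4
#>       k   eta r_squared n_times
#>   <dbl> <dbl>     <dbl>   <int>
#> 1 1.000 0.250         1     401

run <- solve_macro(lv_params(2, 1, 1, 3), 4, 1,
                   mu_closed_form_source(1/4), t_end = 40)
glance(run)
#> # A tibble: 1 × 10
#>       a     b     c     d mu_kind        dt t_end x_final y_final H_drift
#>   <dbl> <dbl> <dbl> <dbl> <chr>       <dbl> <dbl>   <dbl>   <dbl>   <dbl>
#> 1     2     1     1     3 closed_form 0.001    40    2.36    4.94    1.19

equilibrium_classical(lv_params(2, 1, 1, 3), method = "numeric")
#> # A tibble: 1 × 3
#>       x     y method
#>   <dbl> <dbl> <chr>
#> 1     3     2 numeric
```

The recovered rate `eta = 0.250` matches the rate the kinetic run was
driven with (`k = 4η` is the decay constant of the squared L2 distance).
The root-found equilibrium `(3, 2)` is `(d/c, a/b)` at the reference
parameters. The hybrid run's first-integral drift (`H_drift`) is the
transient cost of the learning phase: it vanishes for `mu_constant(1)` and
shrinks window-by-window as `μ → 1`. `autoplot(run)` draws the phase
portrait; `tidy(run)` returns the `t, x, y, mu` trajectory as a tibble.

Full coupled runs are driven by a YAML config
(`run_from_config(example_config("figure2a"), out_dir = "out")`), which
writes trajectory/μ-trace CSVs plus JSON sidecars; `selfcheck()` runs the
fast numerical invariants; `scripts/reproduce_figures.R` regenerates the
reference phase portraits (classical orbit, and hybrid orbits started from
`(4, 1)` vs `(0.1, 9)`) as data and PDFs.

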