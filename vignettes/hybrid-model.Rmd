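---
title: "The hybrid kinetic / Lotka-Volterra competition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid kinetic / Lotka-Volterra competition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridlv)
```

## The model

Two cell populations compete: a tumour population that proliferates and
*hides* by reshaping its biological activity, and an immune population that
must *learn* that activity before its destructive capacity becomes
effective. The model couples two scales.

**Microscopic (kinetic) layer.** Each population $i \in \{1, 2\}$ carries a
probability density $f_i(t, u)$ over a scalar activity $u$. Binary
encounters between a candidate particle of population $i$ (activity
$u_\ast$) and a field particle of population $j$ (activity $u^\ast$) occur
at rate $\eta_{ij}$ and move the candidate to activity $u$ with transition
density $\varphi_{ij}(u_\ast, u^\ast, u)$, a probability density in $u$.
The evolution balances gain and loss:

$$
\partial_t f_i(t,u) = \sum_j \eta_{ij} \iint \varphi_{ij}(u_\ast,u^\ast,u)
f_i(t,u_\ast) f_j(t,u^\ast)\,du_\ast\,du^\ast
\;-\; f_i(t,u) \sum_j \eta_{ij} \int f_j(t,u^\ast)\,du^\ast .
$$

**Learning functional.** The coupling variable is
$\mu(t) = 1 - \int (f_1 - f_2)^2\,du \in [0, 1]$: $\mu = 1$ exactly when the
immune distribution has reproduced the tumour one, and it drops with the
squared $L^2$ distance between the two.

**Macroscopic layer.** Population sizes follow a Lotka–Volterra system in
which only the predation term of the prey (tumour) equation is modulated by
learning:

$$
\dot x = a x - \mu(t)\, b x y, \qquad \dot y = c x y - d y .
$$

The predator equation is deliberately left unmodified — that is what the
model prescribes; a symmetric modification would be an extension, not this
model. With $\mu \equiv 1$ the classical system is recovered, with its
interior equilibrium $(d/c,\, a/b)$ and closed orbits on level sets of
$H(x, y) = c x - d\ln x + b y - a\ln y$. With time-dependent $\mu$ the
instantaneous nullcline intersection is
$\left(d/c,\; a/(b\,\mu(t))\right)$: the $x$-coordinate never moves, while
the $y$-level decreases monotonically to $a/b$ as learning completes. We
compute this point as defined and verify only its limit — for the
nonautonomous system it is a moving nullcline intersection, not an
attractor statement.

## Kernel forms and the closed-form chain

Three kernel representations are supported.

* **General tabulated** (`transition_kernel()`): four $n^3$ arrays, unit
  normalisation in the outgoing index enforced at construction
  (`check_normalization()` reports the worst deviation and where).
* **Separable** (`separable_kernel()`):
  $\varphi_{ij} = \psi_i(u_\ast, u)\,\xi_j(u^\ast, u)$ for $i \ne j$, with
  diagonal components identically zero. Only the *product* integral is
  constrained to 1; any rescaling is absorbed into the factors jointly. The
  zero diagonal is exempted from the universal normalisation check (the two
  requirements are mutually inconsistent as stated; we follow the
  factorised form).
* **Dirac delta** (`delta_kernel()`): $\psi_i = \delta(u - u_\ast)$,
  $\xi_j = \delta(u - u^\ast)$. The delta is *never* discretised on the
  grid — the marker routes the solver to the analytically reduced local
  equations
  $\dot f_1 = \eta_{12} f_1 f_2 - (\eta_{11} + \eta_{12}) f_1$ (and
  symmetrically), which a grid representation could only approximate with
  resolution-dependent error.

With all four rates equal to $\eta$ the difference $f = f_1 - f_2$ obeys
$\dot f = -2\eta f$, so $f(t,u) = f(0,u)e^{-2\eta t}$. From the Gaussian
reference profile $f(0,u) = e^{-u^2}/\sqrt{\pi}$ this yields the closed
form

$$
\mu(t) = 1 - \frac{e^{-4\eta t}}{\sqrt{2\pi}},
$$

which is the package's central analytic oracle: the delta-mode solver, the
quadrature, and the full coupled runner are all checked against it
(`mu_consistency_check()`, `selfcheck()`).

Note two modelling caveats inherited from the formulation itself, which we
surface rather than resolve. First, the reduced separable/delta equations
substitute the unit-mass constraint into the loss term only, so they do not
conserve mass exactly; `mass_drift()` reports the drift and
`run_from_config()` logs it. Second, the abstract requirement "$\mu = 0$
iff one distribution vanishes" is *not* a property of the quadratic-distance
functional (if $f_1 \equiv 0$, $\mu = 1 - \int f_2^2$, not 0); we treat it
as a desideratum of the abstract functional and do not assert it.

## Numerical choices

* **Domain truncation.** The activity domain is unspecified beyond being a
  subset of the real line, and the closed-form chain integrates over the
  whole line. We truncate to $[-6, 6]$: $e^{-u^2} < 3\times10^{-16}$ at
  $|u| = 6$, so the truncation error sits below double-precision quadrature
  noise and both conventions are served.
* **Quadrature.** Composite Simpson on a uniform grid with an odd node
  count; weights are trivially testable and the rule is exact for cubics.
  Default 241 nodes (spacing 0.05). One honest subtlety: for rapidly
  decaying smooth integrands such as Gaussians, Simpson inherits the
  trapezoid rule's superalgebraic convergence, so the textbook
  fourth-order error ratio is only observable on integrands with nonzero
  boundary derivatives (the test suite uses $\cos u$ for the order check
  and asserts the Gaussian integrals directly at $10^{-10}$).
* **Time integration.** Classical fixed-step RK4 for both layers (kinetic
  default $dt = 0.01$; macroscopic default $dt = 10^{-3}$, horizon 40 —
  several orbit periods at the reference parameters, seconds of runtime).
  The order is verified against the analytic decay oracle by step halving
  in the truncation-dominated regime ($dt = 0.1 \to 0.05$); at
  $dt = 0.01$ the oracle error is already near the roundoff floor.
  Non-finite states abort with the failure time.
* **Mass is a linear invariant.** For a fully normalised kernel the
  semidiscrete gain and loss integrals cancel for *every* state, so RK4
  conserves each population's mass to roundoff — conservation over a run is
  a genuine test of the discrete collision balance, not of step size.
* **Coupling interpolation.** A kinetic-sourced $\mu$ trace is interpolated
  linearly in $t$ between recorded steps (constant beyond the ends). The
  $O(\Delta t^2)$ interpolation error is far below the tolerance at the
  default steps; the closed-form source avoids interpolation entirely by
  evaluating $\mu$ at every internal RK4 stage time.
* **Clamping.** The quadratic form does not guarantee
  $\int (f_1-f_2)^2 \le 1$; when it exceeds 1, $\mu$ is clamped to 0 with a
  warning (and counted in run logs) instead of raising — a running
  simulation should degrade gracefully while surfacing the violation.
  Likewise a density's pointwise bound of 1 is a warning only: a narrow
  normalised density legitimately exceeds 1.
* **Root-finding.** The numerical equilibrium uses `pracma::fsolve` from
  the reference start, polished by Newton steps with the analytic Jacobian
  to reach $10^{-10}$ agreement with $(d/c, a/b)$.

## The fixture generators, and what they do not emulate

`random_density()` draws a smooth, strictly positive, unit-mass density
(softplus-tempered random Fourier series), deterministic per seed.
`make_separable_fixture()` builds a separable kernel whose product
constraint holds for *every* pair of incoming activities, to solver
precision: the $\psi_i$ rows are convex mixtures of $m = 3$ fixed
quadrature-normalised Gaussian bumps with smoothly varying mixture weights,
and $\xi_j = 1 + \beta_j(u^\ast)\, v(u)$ where $v$ is a smooth bump
projected (a small Gram-system solve) to be discretely orthogonal to every
mixture component and $|\beta_j| \le 0.45$ keeps $\xi_j$ positive. A naive
per-pair rescaling cannot be stored in separable factors unless it
factorises, which is why the construction enforces the constraint through
orthogonality instead.

The initial condition of the coupled reference run is pinned down only
through the *difference* of the two densities; `split_difference()` adds
the Gaussian reference difference to a seeded base density. Under equal
rates the evolved difference is provably independent of the split, and the
suite verifies this numerically.

These generators emulate smooth unimodal-to-mildly-multimodal activity
distributions and smooth interaction kernels. They do not emulate heavy
tails, sharp phenotypic switching, kernels that depend on time or on the
population sizes, or more than two populations — passing tests therefore
say nothing about such regimes; they certify the numerics and the model
chain on smooth desk-scale inputs.

## Problem sizes and defaults

| quantity | default | notes |
|---|---|---|
| activity domain | $[-6, 6]$ | truncation error $< 3\times10^{-16}$ for the reference profiles |
| grid nodes | 241 (general tabulated kernels: 61) | $O(n^3)$ memory/work per tabulated component |
| kinetic step | $dt = 0.01$ | oracle error $\ll 10^{-6}$ at $t = 2$ |
| macro step | $dt = 10^{-3}$, horizon 40 | $H$ drift $< 10^{-4}$ over $t \le 20$ |
| encounter rate (reference) | $\eta = 1/4$ | equal-rate closed-form chain |
| LV parameters (reference) | $a = 2$, $b = c = 1$, $d = 3$ | equilibrium $(3, 2)$ |
| separable fixture mixture size | $m = 3$ | richer $m$ raises cost, not coverage |

## Known limitations

Fixed-step integration only (no adaptivity or stiffness control); two
populations; one scalar activity; the quadratic-distance learning
functional only (no $L^1$/Hellinger variants); kernels independent of time
and of population sizes. The reduced kinetic modes drift in mass by
construction — use the full separable mode when mass conservation matters,
and watch `mass_drift()` either way.
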