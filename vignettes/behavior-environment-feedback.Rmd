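---
title: "Coupled behavior-environment dynamics: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled behavior-environment dynamics: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behenv)
```

## The model

A population of $N$ agents each expresses one of two behaviors: a *baseline*
behavior $B$ with per-capita environmental impact $l_B$, or an *active*,
proenvironmental behavior $A$ with smaller impact $l_A$ ($0 < l_A < l_B$).
The population state is the frequency $x \in [0,1]$ of active agents. A
single *perceived environmental state* $e \in [l_A, l_B]$, shared by all
agents, summarizes how degraded the environment currently feels; it relaxes
logistically toward the population's mean per-capita impact,

$$\frac{de}{dt} = h(x,e) = \ell\, e\,\bigl(l_A x + l_B(1-x) - e\bigr),$$

at a pace set by the *environmental reactivity* $\ell$. Note that $e$ is
informational, not physical: it tracks intentions and visible action, which
is why it can respond on the same fast timescale as behavior while the
physical environment is effectively frozen.

Agents switch behavior through two channels.

* **Social imitation.** Encounters occur at rate scale $\kappa$; an
  encounter converts an agent toward $A$ with attractiveness
  $\lambda_A(x) = \gamma_A + \delta_A x$ and toward $B$ with
  $\lambda_B(x) = \gamma_B + \delta_B (1-x)$, combining the payoff
  $\gamma_i$ of the target behavior with a conformist pull $\delta_i$
  proportional to its current frequency.
* **Individual assessment.** Independently of encounters, an agent
  switches toward $A$ at rate $\tau_A(e) = \tau (e - l_A)$ and toward $B$
  at rate $\tau_B(e) = \tau (l_B - e)$: the further the perceived state
  sits from a behavior's own impact, the stronger the pull toward that
  behavior. The *sensitivity* $\tau$ sets this channel's timescale.

In the large-$N$ limit the frequency obeys

$$\frac{dx}{dt} = p(x,e) = \kappa x(1-x)\bigl(\lambda_A(x)-\lambda_B(x)\bigr)
  + \tau_A(e)(1-x) - \tau_B(e)x .$$

Only two combinations of the social parameters matter: the *payoff
differential* $\beta = \gamma_A - \gamma_B$ (negative when the active
behavior is costly) and the *social norm threshold*
$\nu = \delta_B/(\delta_A+\delta_B)$, the unstable frequency that
conformism must be pushed past when $\beta = 0$. The package therefore
accepts parameters either in raw form (`model_params()`) or as
$(\beta, \nu)$ plus anchors (`params_from_differentials()`); the anchors
$\kappa = 1$, $\gamma_B = 1$, $\delta_B = 0.5$, $l_B = 1$ are the
conventional defaults used throughout.

The aggregate per-capita switching intensity

$$\Omega(x,e) = \kappa x(1-x)\bigl(\lambda_A(x)+\lambda_B(x)\bigr)
  + \tau_A(e)(1-x) + \tau_B(e)x$$

measures behavioral *inconsistency*. We call the active behavior
**consistently adopted** at a stable equilibrium $(x^*, e^*)$ when $x^*$ is
high and $\Omega(x^*, e^*)$ is low; the package operationalizes "high" and
"low" as $x^* \ge 0.9$ and $\Omega \le 0.05$ by default
(`consistency_check()`), both configurable and recorded in every sweep
output. Near full adoption the identity
$\Omega(1, l_A) = \tau\,(l_B - l_A)$ makes the product of sensitivity and
impact differential the natural consistency scale.

## Equilibria, stability and regimes

At any equilibrium the environment must sit on the mixture line
$e^* = l_A x^* + l_B (1 - x^*)$, so fixed points are roots in $[0,1]$ of
the cubic $p_0(x) + \tau (l_B - l_A)(1 - 2x)$
(`reduced_polynomial()`). Roots are computed from companion-matrix
eigenvalues — robust when $\kappa$ or the social terms vanish and the
degree collapses — then polished with two Newton steps; roots closer than
$10^{-8}$ are merged and roots within $10^{-10}$ of the boundary are
clipped. When $\tau = 0$ the cubic factorizes exactly as
$\kappa x (1-x)(a + bx)$ and the roots
$\{0,\, 1,\, (\delta_B-\beta)/(\delta_A+\delta_B)\}$ are taken in closed
form, so that boundary equilibria are exact and $\Omega$ vanishes there
identically.

Stability comes from the Jacobian of $(p, h)$, whose coupling entry
$\partial p/\partial e = \tau$ is exact. An equilibrium is labelled stable
or unstable when the largest eigenvalue real part clears a margin of
$10^{-9}$; otherwise it is *marginal*, and `classify_regime()` re-classifies
it by perturbing and integrating rather than guessing, since parameter
grids occasionally land on bifurcation boundaries. One derivation detail
worth recording: the drift coefficient of the frequency fluctuation
equation is the full derivative
$\partial p/\partial x = \kappa[(1-2x)(a+bx) + bx(1-x)] - \tau(l_B-l_A)$
with $a = \beta - \delta_B$, $b = \delta_A + \delta_B$; the package uses
this exact form (validated against central finite differences in the test
suite) everywhere the linearization appears.

Three regimes exhaust the phase diagram: *monostable*, *bistable* (two
stable equilibria flanking an unstable threshold) and *limit cycle*. The
box $[0,1] \times [l_A, l_B]$ is forward-invariant, so when the unique
equilibrium is unstable the Poincar&eacute;&ndash;Bendixson theorem
guarantees an attracting periodic orbit — a unique saddle is impossible by
the index argument — and `classify_regime()` labels such cells analytically
without integrating. `detect_limit_cycle()` measures the orbit when asked:
it discards a transient of $10/\min(|\mathrm{Re}\,\lambda|, \ell)$ time
units (capped at 1000), locates successive maxima of $x$, refines each
peak time by local quadratic interpolation, and reports the mean peak
spacing as the period; if the last peak heights have not stabilized the
result is flagged *inconclusive*, never coerced. Degenerate tangency
configurations are reported as monostable with a warning rather than
inventing a fourth regime name.

## Exact finite-N simulation

`simulate_pdmp()` simulates the finite-population process exactly by
thinning (uniformization). Candidate times are exponential at the
dominating rate

$$\xi_N = N\bigl[\kappa(\gamma_A+\gamma_B+\max(\delta_A,\delta_B))
  + \tau(l_B-l_A)\bigr](1+10^{-12}),$$

which bounds the total event rate $N\,\Omega$ everywhere because
$\lambda_A + \lambda_B$ is affine in $x$ (supremum at an endpoint) and
$\tau_A + \tau_B$ is constant. At each candidate one of four channels —
social $B{\to}A$, social $A{\to}B$, assessment $B{\to}A$, assessment
$A{\to}B$ — fires with probability rate$/\xi_N$, else the candidate is a
phantom. The four channels are logged separately and can be aggregated to
the three observable outcomes (no change, $B{\to}A$, $A{\to}B$) when
reporting.

Between candidates $x$ is constant, which makes the environment flow
autonomous and solvable: the default update uses the exact logistic
solution $e(dt) = c\,e/(e + (c-e)e^{-\ell c\,dt})$ with
$c = l_A x + l_B(1-x)$, removing one discretization error at zero cost. An
explicit Euler update with capped step remains available
(`env_update = "euler"`) for fidelity checks against step-based
references. The simulator runs on R's RNG, so a single integer seed makes
runs bit-reproducible; the seed, the dominating rate and the full
configuration are embedded in every run object and its JSON sidecar.
Event logging is refused above $10^7$ expected candidates in favor of
grid sampling, to bound memory on long bistable runs.

Setting $\ell = 0$ freezes the perceived environment. This is exposed
deliberately as a calibration device: with $e$ frozen the jump chain is a
birth-death process on $\{0, 1/N, \dots, 1\}$ whose stationary law follows
from detailed balance, and the test suite checks the simulator's long-run
occupancy against it (total-variation distance below 0.05 at $N = 50$).

## Fluctuations: the linear-noise view

Writing $(X^N, E^N) = (x, e) + N^{-1/2}(\eta^A, \eta^E)$, the scaled
fluctuations converge to a linear (Ornstein-Uhlenbeck-type) process whose
drift is the Jacobian of $(p,h)$ along the deterministic path and whose
noise enters the *behavior coordinate only*, with infinitesimal variance
$\Omega(x,e)$ — switching intensity and fluctuation strength are the same
number. At a stable equilibrium the stationary covariance $\Sigma$ solves
the Lyapunov equation $A\Sigma + \Sigma A^\top + D = 0$ with
$D = \mathrm{diag}(\Omega(x^*,e^*), 0)$; the environment coordinate
inherits variance purely through the drift coupling, so
$\Sigma_{22} > 0$ whenever $\tau > 0$ and $\Omega(x^*,e^*) > 0$.

Two related scalars are easy to conflate, so `stationary_covariance()`
reports both, clearly labelled: the *diffusion value* $\Omega(x^*,e^*)$,
which is the headline consistency quantity, and the Lyapunov variance
$\Sigma_{11}$, which rescales $\Omega$ by the relaxation rates and is what
$N\cdot\mathrm{Var}(X^N)$ actually converges to. The Euler-Maruyama
simulator `simulate_ou()` uses noise amplitude $\sqrt{\Omega}$ so that the
infinitesimal variance is $\Omega$, consistent with the quadratic-variation
derivation.

## What the tests do and do not show

All experiments are generated internally; there is no external data. The
test suite and the acceptance script validate, at desk scale:

* the closed-form identities (rate sums, boundary drifts, the
  $\Omega(1,l_A)$ identity, the $\tau=0$ equilibrium triple);
* equilibria from the cubic against long-horizon ODE attractors from
  random starts;
* the full stochastic pipeline: PDMP ensemble means track the ODE within
  Monte-Carlo error (50 runs at $N = 10^4$ over 50 time units), the scaled
  stationary variance is $N$-free across $N \in \{10^3, 10^4\}$, and the
  three routes to the stationary fluctuation variance — Lyapunov solve,
  Euler-Maruyama simulation, $N$-scaled PDMP ensembles — agree within a
  few percent / Monte-Carlo standard errors;
* regime-map topology: the $\tau = 0$ sweep reproduces the closed-form
  bistability region cell-for-cell on a $101{\times}101$ grid of cell
  centers ($\beta \in [-1,1]$, $\nu \in (0,1]$; centers avoid all
  boundary coincidences by an exact parity argument), strong feedback
  ($\tau = 10$) pins the unique equilibrium near $1/2$ over most of the
  plane, and limit-cycle cells appear only at intermediate
  $\tau(l_B-l_A)$ with small $\ell$ and are suppressed when $\ell$
  increases;
* stochastic basin switching: at the bistable reference point
  ($\beta=-0.25$, $\nu=0.3$, $\tau=0.1$, $\ell=0.1$, $l_A=0.7$) a single
  run at $N = 100$ over $2\times 10^4$ time units visits
  $0.1$-neighborhoods of both stable equilibria.

These are checks of internal mathematical consistency under the model's
own assumptions — a well-mixed population, identical agents, a shared
perceived environment with purely negative feedback, and constant payoffs.
Passing them says nothing about heterogeneous sensitivities, network
structure, positive reinforcement ("improved environment encourages
more"), or any empirical population; those are outside the model class.

## Parameter choices and study conditions

$\tau$ and $\ell$ have no defensible default — they set the two timescale
ratios the whole analysis is about — so the package refuses to invent one
and instead ships the preset grids `behenv_presets` ($\tau \in \{0.1, 1,
10\}$: assessment slower than, matched to, faster than social encounters;
$\ell \in \{0.1, 0.25\}$: slow and moderately fast environments). The
bistable reference point used in examples and acceptance runs
reconstructs the costly-behavior, weak-feedback corner with $\tau = 0.1$
and $N = 100$ for the switching experiment; neither value is dictated by
theory, and the qualitative behavior (bistability plus rare basin
crossings) is robust to moderate changes.

The incremental-substitution scenario chains stages in which each
consistently adopted behavior becomes the next baseline
(`incremental_scenario`): stage $k{+}1$ inherits $l_B$ from stage $k$'s
$l_A$, and starts from $x = 0$ — legitimate because with $\tau > 0$ the
assessment channel lifts the new behavior from strict absence,
$p(0, e) = \tau(e - l_A) > 0$. The shipped six-stage ladder steps the
impact down by 0.05 per stage under strengthening social pressure,
demonstrating a monotone decrease of the equilibrium perceived impact
$e^*$ from 0.95 to 0.70 even as the behavior grows costlier.

## Numerical choices

* **Integration**: adaptive Runge-Kutta 4(5) (`deSolve::ode`, method
  `ode45`) with `rel_tol = 1e-8`, `abs_tol = 1e-10`, dense output every
  0.1 time units. The system is smooth and non-stiff across the
  admissible parameter ranges; slow $\ell$ only lengthens horizons.
* **Domain handling**: the box is forward-invariant analytically but not
  bit-exactly; states within $10^{-12}$ of the boundary are clamped,
  anything further out is a genuine domain error.
* **Equilibrium declaration**: a trajectory is "at equilibrium" when the
  terminal drift satisfies $\|(p,h)\|_\infty < 10^{-8}$; scenario stages
  instead require the terminal state within $10^{-4}$ of a stable root of
  the cubic, which is robust to the integrator plateauing at its own
  tolerance.
* **Problem sizes**: the heavy checks run 50 ensembles at $N=10^4$ over
  50 time units, 6-8 stationary runs over 300-400 time units, a
  $5\times10^5$-step Euler-Maruyama path, and $101^2$ / $41^2$ sweep
  grids. These sizes give Monte-Carlo errors a factor of a few below the
  tolerances they are tested against.

## A worked example

```{r example, eval = FALSE}
p <- params_from_differentials(beta = -0.25, nu = 0.3, tau = 0.1,
                               ell = 0.1, l_A = 0.7)
find_equilibria(p)          # two stable states flanking a threshold
classify_regime(p)$regime   # "bistable"

run <- simulate_pdmp(p, N = 100, x0 = 0.05, e0 = 1, t_end = 20000,
                     seed = 1, grid_dt = 1)
range(run$grid$x)           # visits both basins

s <- stationary_covariance(max(find_equilibria(p)$x_star), p)
s$diffusion_value           # Omega(x*, e*): the consistency scale
s$stationary_cov            # what N * Var(X^N, E^N) converges to
```
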