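---
title: "Methods: the adaptive-network SIS model and its numerical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive-network SIS model and its numerical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`animfa` studies the planar system

$$\frac{dy}{dt} = -y + \tau y (1-y) z, \qquad
  \frac{dz}{dt} = -\zeta z f_{br}(y) + \xi (1-z) f_{cr}(y),$$

on the unit square. The prevalence equation is the mean-field SIS
(NIMFA-type) equation for a well-mixed population whose average contact
density is $z$; the link-density equation balances a link-breaking process
at rate $\zeta f_{br}(y)$ acting on existing links and a link-creation
process at rate $\xi f_{cr}(y)$ acting on absent links. Time is measured
in units of the mean infectious period: `rescale_parameters()` divides all
raw rates by the curing rate $\delta$, so $\tau = \beta/\delta$ is the
effective infection rate and $\omega = \zeta/\xi$ the effective
link-breaking rate. All parameters are dimensionless and positive.

Standing assumptions, enforced by `validate_pair()`:

* $f_{br}, f_{cr} \ge 0$ on $[0,1]$ (checked on a 10 001-point uniform
  grid, with negativity below $10^{-12}$ absorbed as roundoff);
* not both responses identically zero (otherwise $z$ is frozen and the
  model degenerates to static SIS);
* continuity plus finite one-sided derivatives. Only continuity is needed
  for simulation; the Jacobian-based classification additionally uses
  $f'_{br}, f'_{cr}$. Supplied analytic derivatives are cross-checked
  against central differences at $10^{-6}$; non-differentiable inputs are
  flagged by validation, not rejected, and fall back to numeric
  differentiation (central differences with step $h = 10^{-6}$,
  second-order one-sided stencils at the interval ends — the responses in
  practice are low-order polynomials, for which this balances truncation
  and roundoff near $10^{-10}$).

The square $[0,1]^2$ is forward invariant for the exact flow: on each face
the field points inward or is tangent ($dy/dt|_{y=0} = 0$,
$dy/dt|_{y=1} = -1$, $dz/dt|_{z=0} = \xi f_{cr} \ge 0$,
$dz/dt|_{z=1} = -\zeta f_{br} \le 0$). Numerically we therefore clamp
states to the square only post-step and only within $10^{-9}$; a larger
excursion is treated as solver failure rather than silently corrected,
since it signals tolerances inconsistent with an invariant region.

## Built-in response pairs

| name | $f_{br}$ | $f_{cr}$ | behaviour |
|---|---|---|---|
| `rlad` | $1$ | $1$ | rewiring independent of the epidemic |
| `linear_breaking` | $y$ | $1$ | breaking proportional to prevalence |
| `asis` | $2y(1-y)$ | $(1-y)^2$ | adaptive SIS: breaking needs S–I contact, creation between susceptibles |
| `aid` | $(1-y)^2$ | $2y(1-y)$ | information diffusion: links created when the item is prevalent |

The factor 2 in the `asis`/`aid` responses is the conversion factor
inherited from the underlying Markovian network derivation and is kept
verbatim for consistency with that literature. User-supplied responses are
accepted either as R functions or as expression strings in a restricted
grammar (`y`, arithmetic, `exp`, `log`); the expression path enables exact
symbolic differentiation via `stats::D()`.

For `rlad` the link equation decouples and the model reduces, with $z$
held at its limit $1/(1+\omega)$, to a logistic prevalence equation.
`rlad_closed_form()` evaluates that reduction with steady state
$y_E = 1 - (1+\omega)/\tau$ and growth rate $K = \tau/(1+\omega) - 1$:
substituting the logistic solution back into
$dy/dt = -y + \tau y(1-y)/(1+\omega)$ fixes the rate at $\tau z^* - 1$
with $z^* = 1/(1+\omega)$ (the familiar $\tau - 1$ is the complete-graph
limit $\omega \to 0$), and the unit tests verify the closed form against
direct integration of the reduced ODE to $10^{-8}$.

## Equilibria, stability, and reproduction numbers

The disease-free equilibrium (DFE) is $y = 0$,
$z_0 = f_{cr}(0) / (\omega f_{br}(0) + f_{cr}(0))$ when the denominator is
positive. When both responses vanish at $y=0$ the whole segment
$\{y = 0, z \in [0,1]\}$ consists of equilibria; the package reports this
as a `dfe_family` and assigns no definite stability label, because one
Jacobian eigenvalue is exactly zero everywhere on the family and linear
analysis is inconclusive. A representative point of the family can still
be interrogated via the `z_family` argument.

Endemic equilibria are the roots $y_E \in (0,1)$ of

$$\omega f_{br}(y) - (\tau - 1) f_{cr}(y) + \tau y f_{cr}(y) = 0,$$

paired with $z_E = 1/(\tau(1 - y_E))$; roots with $z_E \notin (0,1]$ are
infeasible and $y_E = 1$ never qualifies. Root finding is a dense sign
scan (2 001 uniform points on $[10^{-9}, 1-10^{-9}]$) with brackets
refined by `uniroot` to $10^{-14}$ interval width and duplicates merged
within $10^{-8}$. Tangential double roots — the fold where a saddle-node
pair is born — produce no sign change, so interior local minima of the
absolute residual are additionally polished and accepted below $10^{-10}$,
tagged with `multiplicity = 2`. The scan density is a deliberate
trade-off: it resolves every pair of roots separated by more than about
$10^{-3}$, ample for polynomial-like responses, but pathological
user-supplied responses with tighter root clusters can defeat it (a
documented limitation; raise `scan_points` in that case). Every returned
equilibrium re-evaluates the full vector field independently and must have
residual $\le 10^{-10}$.

Stability is classified from the Jacobian

$$J = \begin{pmatrix} -1 + \tau(1-2y)z & \tau y (1-y) \\
 -\zeta z f'_{br}(y) + \xi(1-z) f'_{cr}(y) &
 -\zeta f_{br}(y) - \xi f_{cr}(y)\end{pmatrix},$$

with a tolerance of $10^{-8}$ on eigenvalue real parts; real parts within
tolerance of zero yield the literal label `undetermined`, which is
propagated to reports rather than silently resolved — boundary cases (e.g.
$\tau$ exactly at threshold) genuinely are undecidable by linearisation.

Two notions of reproduction number coexist and both are implemented. When
$f_{cr}(0) > 0$, the next-generation splitting of the DFE Jacobian's
prevalence entry gives $R_0 = \tau f_{cr}(0)/(\omega f_{br}(0) +
f_{cr}(0))$, and $R_0 > 1$ guarantees at least one endemic equilibrium.
When $f_{cr}(0) = 0$ (as for `aid`) the splitting is undefined and the DFE
never loses stability; `critical_threshold()` then locates the value of
$\tau$ at which the endemic-equilibrium *count* changes, by bisection to a
requested bracket width (default $10^{-6}$). The threshold result reports
the counts on both sides rather than asserting which bifurcation occurred;
distinguishing transcritical from saddle-node is left to the caller (a
DFE-coincidence check suffices in the regular cases).

## Global structure

**No limit cycles.** With the Dulac multiplier $\phi = 1/(yz)$ the
divergence of the scaled field is $F(y,z) = -\tau - \xi f_{cr}(y)/(yz^2)$,
strictly negative on the open square for every admissible pair, so
periodic orbits are impossible and every bounded orbit settles at an
equilibrium. `verify_no_limit_cycles()` certifies the sign condition on an
interior lattice (default $201 \times 201$) and reports the maximum and
its location; this is a numerical certificate at lattice resolution, not a
proof, but the expression is monotone enough that the lattice is adequate
for continuous responses.

**Regions of attraction.** Around a stable equilibrium the package solves
the $2\times 2$ Lyapunov equation $PJ + J^\top P = -I$ exactly (a $4\times
4$ linear solve; residual is checked at $10^{-12}$) and evaluates
$\hat V(x) = (x-x_E)^\top P (x-x_E)$ together with its orbital derivative
$d\hat V/dt = 2(x-x_E)^\top P f(x)$ — the exact gradient of the quadratic
form contracted with the *full nonlinear* field, not a finite difference
along orbits — on a lattice (default $401\times 401$; the test suite uses
$201\times 201$, which resolves the same regions at a quarter of the
cost). The admissible level $c^*$ is the largest $c$ whose sublevel set
contains no lattice point with $d\hat V/dt \ge 0$ other than the
equilibrium itself, found by bisection to $10^{-6}$ relative tolerance.
The resulting set is a *sound inner estimate*: the tests forward-simulate
every lattice point of $\Omega_{c^*}$ and verify convergence to the
equilibrium. It is also expectedly conservative — a quadratic form cannot
follow a curved basin boundary, and the underestimate is substantial for
the endemic attractor in the bistable example; the basin map, not the
Lyapunov estimate, is the authoritative picture.

**Separatrix.** In the bistable regime the dividing curve is the stable
manifold of the interior equilibrium between the attractors. At the
reference parameters ($\tau = 3$, $\zeta = \xi = 1$, `aid`) that
equilibrium has $\det J = -2/9 < 0$: it is a saddle, and the curve is
computed by backward-time integration from $\pm 10^{-6}$ displacements
along the stable eigenvector, clipped to the square. Because classifying a
near-threshold interior equilibrium as saddle versus unstable node is
numerically delicate, an independent construction is also provided:
attractor-boundary bisection along lattice columns to $10^{-6}$. Results
record which method produced them, and the basin map provides a
consistency check (label-versus-side agreement).

**Basin maps.** `basin_map()` forward-simulates a lattice of initial
conditions (default horizon 500 rescaled time units) and labels each point
by the equilibrium its orbit reaches within $10^{-6}$; points that have
not settled are labelled `unresolved`, never forced. Lattices are
integrated as stacked ODE systems in chunks with a non-stiff
adaptive solver, which is orders of magnitude faster in R than per-point
integration and is also used for the region-of-attraction soundness
checks.

## Slow network dynamics

When rewiring is slow relative to transmission the model is a standard
slow-fast system: $dz/dt$ is scaled by $\varepsilon \in (0,1)$, with the
link-creation rate absorbed into $\varepsilon$ (so $\zeta$ remains the
only free slow rate — an asymmetry we keep deliberately, and expose in
`simulate_slowfast()`). The critical manifold is the disease-free axis
together with the branch $y = (\tau z - 1)/(\tau z)$, $z \ge 1/\tau$
(non-empty only for $\tau > 1$); layer eigenvalues are $\tau z - 1$ and
$1 - \tau z$ respectively, with exchange of stability at the
non-hyperbolic point $(0, 1/\tau)$.

An orbit hitting the axis at $z_{in} < 1/\tau$ exhibits delayed loss of
stability: it drifts along the axis past $1/\tau$ while the prevalence is
exponentially small, and erupts at the $z_{out} > 1/\tau$ where the
accumulated fast contraction and expansion cancel:

$$\int_{z_{in}}^{z_{out}} \frac{\tau z - 1}{g_0(z)}\,dz = 0,
  \qquad g_0(z) = -\zeta z f_{br}(0) + \xi (1-z) f_{cr}(0).$$

The entry-exit construction requires $g_0 > 0$ on $[z_{in}, 1)$ (the slow
flow must actually transport the orbit past $1/\tau$), which forces
$f_{br}(0) = 0$; the weighting by a general $g_0$ rather than the
constant-creation special case $\xi(1-z)$ follows the entry-exit
literature and is recorded in results as the method used. With
$f_{br}(0)=0$ the antiderivative
$(-\tau z - (\tau-1)\log(1-z))/(\xi f_{cr}(0))$ is available in closed
form; a quadrature route (adaptive integration, bisection on the
cumulative integral to $10^{-10}$, bracket grown geometrically toward the
logarithmic singularity at $z = 1$) is kept as an independent cross-check
and the two agree to $10^{-9}$ in the tests. The singularity also implies
$z_{out} < 1$ strictly for every admissible entry point.

Comparing the asymptotic map against stiff simulation requires choosing
what "entering a neighbourhood of the axis" means; we use crossings of
$y = 0.01$ (configurable, recorded in output metadata), detect entry/exit
by linear interpolation on a dense output grid (adequate because $z$ moves
at $O(\varepsilon)$), and feed the *observed* entry point to the map. At
$\varepsilon = 0.01$ the predicted and simulated eruption densities agree
within 0.05, and the discrepancy shrinks monotonically over
$\varepsilon \in \{0.05, 0.02, 0.01\}$ in the test suite.

## Numerical defaults and problem sizes

* Integrators: `lsodar` (stiffness-switching, with root functions for
  convergence detection) for single trajectories at relative/absolute
  tolerances $10^{-8}/10^{-10}$; `ode45` for batched lattices; `lsoda` at
  $10^{-10}/10^{-12}$ for slow-fast runs, where the dormant prevalence
  reaches $\sim 10^{-5}$ and must be resolved accurately.
* Convergence: vector-field norm below $10^{-9}$, or distance below
  $10^{-6}$ to a precomputed equilibrium (ties broken by nearest).
* Test-suite problem sizes: $10\times 10$ $(\tau,\omega)$ closed-form
  grids; 150 random supercritical draws for the existence property;
  $201\times 201$ Dulac and basin lattices; $201\times 201$
  region-of-attraction lattices with full soundness simulation; four
  entry-exit comparisons plus a three-point $\varepsilon$ sweep.
* Determinism: every randomised check runs under a fixed seed; identical
  configuration and seed give byte-identical CSV artifacts.

## What the model does and does not capture

The model is a deterministic mean-field description of a well-mixed
population whose entire contact structure is summarised by one scalar
density. Passing the test suite therefore says nothing about
finite-network fluctuations, degree heterogeneity, community structure,
stochastic extinction at low prevalence, or reporting delays — all of
which matter in real epidemic data. Within the model class, the absence of
limit cycles is a structural fact: recurring epidemic waves require
mechanisms beyond prevalence-driven rewiring (seasonality, loss of
immunity, delays). The Lyapunov regions are inner estimates only, and the
threshold detector reports equilibrium counts, not bifurcation types.
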