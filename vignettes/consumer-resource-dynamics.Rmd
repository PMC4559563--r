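---
title: "Consumer–resource competition in chemostats: model, equilibria, stability, transients"
author: "chemocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumer-resource competition in chemostats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocomp)
```

## The model and its assumptions

The package implements the classical consumer–resource competition model in
the Tilman tradition. For consumer densities $N_i(t)$ and resource densities
$R_j(t)$,

$$\frac{dN_i}{dt} = \bigl(f_i(R_1,\dots,R_m) - m_i\bigr)\,N_i, \qquad
\frac{dR_j}{dt} = a_j\,(s_j - R_j) - \sum_i q_{ji}\, f_i\, N_i .$$

The structural assumptions are those of the model family, not numerical
conveniences:

* **No direct interaction** between consumers or between resources; all
  coupling runs through consumption.
* **Chemostat supply**: each resource relaxes exponentially towards its
  stable level $s_j$ at dilution rate $a_j$, independently of the others.
* **Growth is monotone in every resource and zero at zero resource.** Two
  concrete growth models are provided: Holling type II,
  $f(R) = f_{\max} R/(R+k)$, for a consumer on one resource, and the Liebig
  minimum $f = f_{\max}\min_j R_j/(R_j+k_j)$ for essential resources.
* **Constant conversion factors** $q_{ji}$: producing one unit of consumer
  $i$ removes a fixed amount $q_{ji}$ of resource $j$ (inverse yields).
* **Closure**: a consumer absent at $t=0$ stays absent forever; the model is
  fully deterministic, with no immigration and no stochastic demography.

All quantities are in dimensionless model units. Rates ($a$, $m$, $f_{\max}$,
eigenvalues) carry dimension 1/time; $k$, $s$ and all state variables are
densities; $q$ is dimensionless. Rescaling all densities together with all
$k$ and $s$ by a common factor leaves every rate unchanged (this scale
covariance is asserted in the test suite).

## Closed-form stationary points

For at most two consumers and two resources every stationary point is
available in closed form; `find_all_equilibria()` enumerates them with
feasibility flags (all densities $\ge 0$, with a $-10^{-12}$ tolerance for
float noise at thresholds).

* **Supply point** (trivial equilibrium): all consumers absent, $R_j = s_j$.
* **Critical resource level**: growth balances mortality at
  $R^* = k\,m/(f_{\max}-m)$, which exists only when $f_{\max} > m$. With one
  resource, the consumer density follows from the resource balance,
  $B^* = a_R(s_R - R^*)/(q_{RB}\, m_B)$; the point is feasible iff
  $R^* < s_R$, equivalently $f_{\max} > m\,(1 + k/s)$
  (`coexistence_threshold_f_max()`).
* **One consumer on two essential resources**: the zero-growth isocline is
  L-shaped with its corner at the two critical levels. Consumption confines
  the resource pair to the supply line through $(s_P, s_R)$ with slope
  $a_R q_{P}/(a_P q_{R})$. Because that slope is positive, the line meets
  exactly one arm of the isocline (or its corner). The implementation
  evaluates both arm candidates and keeps the one whose other coordinate
  clears its critical level; an exact tie is the corner case, which is
  returned flagged `on_corner`, never silently resolved. When the supply
  point lies below the isocline the intersection carries a negative consumer
  density and is returned infeasible — no "missing intersection" case
  exists.
* **Two consumers on two resources**: branch pairings of the two L-shaped
  isoclines give at most two candidate resource intersections; for each
  consistent pairing the densities solve
  $Q\,(m_A A, m_B B)^{\mathsf T} = \bigl(a_P(s_P-P^*),\,a_R(s_R-R^*)\bigr)^{\mathsf T}$
  with $Q$ the conversion matrix. Feasibility (both densities positive) is
  equivalent to the supply point lying in the wedge spanned by the
  consumption vectors; the test suite asserts this equivalence on randomized
  systems rather than trusting either form alone. A singular $Q$
  (proportional consumption ratios) is a hard error: the densities are then
  not determined.

## Stability classification

`classify()` computes the eigenvalues of the analytic Jacobian and labels
the point by the sign pattern of the real parts: `saddle`, `stable_node`,
`stable_vortex` (complex pair), `unstable_node`/`unstable_vortex` (never
observed for this model family — a randomized test asserts their absence),
or `non_hyperbolic` when any real part sits within tolerance of zero, in
which case no guess is made.

Numerical choices:

* **Hyperbolicity tolerance** `tol_re = 1e-8 * max(a_j, m_i, f_max_i)` —
  scale-aware, so stiff and slow systems are treated alike. Vortex detection
  uses `tol_im = 1e-10`.
* **Liebig corners**: at an exact tie of the saturation ratios the growth
  value is well defined but the derivative is not; the gradient uses the
  lower-index resource branch and the Jacobian carries an `on_corner` flag.
  Classifications at corners are reported but flagged — no differentiability
  is claimed.
* The **finite-difference Jacobian** (central differences, step
  `1e-6 * max(1, |x|)` per component) is kept as an independent cross-check
  and as the only path for non-smooth situations; analytic and
  finite-difference forms are required to agree to a relative `1e-5` at
  random smooth states.
* For the one-consumer/one-resource coexistence point the closed-form
  eigenvalue pair
  $\lambda_\pm = -\tfrac12 a_R - \tfrac12 qB^*f' \pm \tfrac12\sqrt{(a_R+qB^*f')^2 - 4 m q B^* f'}$
  is implemented independently and checked against the generic eigensolver
  to $10^{-9}$.
* For two-consumer coexistence the determinant sign criterion
  (`coexistence_sign_criterion()`) compares $\operatorname{sign}\det Q$ with
  the sign of the growth-gradient determinant: opposite signs mean a saddle.
  Either determinant below $10^{-12}$ in magnitude yields `"degenerate"`,
  no verdict. Agreement with the eigenvalue classification is asserted on
  500 randomized feasible systems.

Eigenvalue magnitudes matter as much as signs: $1/|\mathrm{Re}\,\lambda|$ is
the timescale on which the system approaches (or escapes) the point, and the
reports include these timescales because transients are governed by the
slowest relevant rate, not by asymptotic stability alone.

## Simulation and transient visits

`integrate_euler()` is a deliberately plain fixed-step forward-Euler scheme
$x_{n+1} = x_n + \Delta t\, f(x_n)$ — first-order, fully deterministic, no
adaptivity, matching how these systems are classically explored. Defaults,
both overridable:

* `dt = 0.01 / max(a_j, m_i, f_max_i)`: one hundredth of the fastest
  timescale in the system.
* `t_end = 100 ×` the slowest timescale among the stable feasible
  equilibria (fallback `100 /` the slowest rate parameter when no closed
  form applies), so even the slowest relaxation completes.

Densities are never clamped: clamping would silently alter the dynamics.
Euler round-off can push a component marginally negative; values down to
$-10^{-6}$ are tolerated and treated as zero inside the growth functions
only, while anything more negative terminates the run with a diagnostic
advising a smaller step (the public `cr_rhs()` is stricter, at $-10^{-9}$).
First-order convergence of endpoints is asserted by a Richardson check
(successive step halvings must shrink the endpoint difference by a factor
of about two).

`detect_visits()` formalises the saddle-lingering narrative: a visit is a
maximal interval during which the trajectory stays within `eps` of a
stationary point for at least `min_dur` time units; when several points
qualify the nearest claims the step, so visits never overlap. The distance
is measured **in the resource subspace by default** (`space = "resource"`),
with `eps = 0.1` and `min_dur = 2`. This was a genuinely open design point
and the resolution is empirical: measured on the two-consumer/two-resource
succession example, the trajectory approaches the supply point no closer
than 0.076 and the B-only saddle no closer than 0.147 in the *full* state
space — a tiny invader density growing from its inoculum keeps the full
state away from the point even while the resources sit on top of it, so a
tight full-state criterion can never register the visits that the phase
plane plainly shows. In the resource plane (where the succession story is
usually told) the visit sequences supply → B-point → coexistence and
supply → B-point → A-point emerge robustly at the defaults. Full-state
distance remains available via `space = "full"` for users who want the
stricter notion.

## Scenario presets

`scenario()` bundles the printed parameter sets of the model family's
standard worked examples (keyed `fig2a` … `fig8`), including initial
states. Two reconstruction notes:

* The two-resource single-consumer table prints a half-saturation label that
  does not exist in the model (`k_PR`); it is read as the R-resource
  half-saturation of the consumer, `k_RB = 1`, which is the only
  interpretation consistent with the surrounding analysis.
* The variant panels `fig4b` and `fig8` do not restate their initial
  consumer densities; the presets reuse the sibling panel's initial state
  (`B(0) = 0.01` for `fig4b`, the `fig5a` start for `fig8`).

`sample_system()` is the property-test generator. It draws parameters
log-uniformly — rates $a, m, f_{\max} \in [0.05, 5]$, densities
$k, s \in [0.1, 5]$, conversions $q \in [0.1, 2]$ — for one of the four
supported configurations, with Holling II growth on one resource and Liebig
growth on two. Log-uniform sampling spreads draws evenly across two orders
of magnitude of timescales, which is what matters for exercising the
scale-aware tolerances. The generator emulates parameter diversity only: it
does not emulate measurement noise, demographic stochasticity, time-varying
supply, or more than two consumers/resources, so passing randomized tests
says nothing about those regimes.

## Problem sizes used in the checks

The randomized suites use 1000 systems for the equilibrium-residual
invariant, 500 feasible systems for the determinant-criterion/eigenvalue
agreement, 100–250 draws for the remaining properties, and simulation
horizons of 200–300 time units for the worked-example trajectories; these
sizes make every property fail loudly under seeded rerandomization while
keeping the default test run in the low minutes on a single CPU.

## Known limitations

* Closed-form equilibria and the determinant criterion cover at most two
  consumers and two resources; larger systems can be simulated but their
  stationary points must be found by other means.
* Exactly coincident critical levels of the two consumers on the same
  resource (isocline arms overlapping) are a measure-zero degeneracy and
  are not enumerated as a continuum; corner intersections are flagged, not
  analysed (no centre-manifold machinery).
* The Euler scheme is first order; it is meant for faithful qualitative
  transients at small steps, not for stiff systems or high-precision
  endpoints. Basin boundaries are explored empirically by simulation only.
* Visit detection depends on `eps`/`min_dur`; the defaults are calibrated
  to the bundled scenarios' scale (densities of order one) and should be
  rescaled for systems living on very different density scales.
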