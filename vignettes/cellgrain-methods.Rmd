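---
title: "From cell-scale forces to tissue-scale pressure: the models behind cellgrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cell-scale forces to tissue-scale pressure: the models behind cellgrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cellgrain)
```

## The two levels of description

`cellgrain` simulates a population of biological cells at two levels and
lets you compare them on the same problem.

On the **microscopic level** every cell is represented individually.  In
the *center-based model* (CBM) a cell is a point center $x_i$; a pairwise
force of signed magnitude $g(r)$ acts along the line between neighboring
centers, repulsive when the cells overlap ($r < s$), adhesive in a band
$s < r < r_A$, and zero beyond the cutoff $r_A$.  Motion is overdamped
(inertia is negligible at cell scales in a viscous environment), so
positions obey first-order dynamics
$\dot x_i = \tfrac1\eta \sum_j \hat r_{ij}\, g(r_{ij})$.
In the *vertex-based model* (VBM) the mesh of cell membranes is the
state: cells are polygons, and forces act on the shared polygon corners.
The Weliky–Oster force weights each of the three edge directions leaving
a vertex by $f(V, a, b) = \varsigma/V + \kappa(a + b)$, where $V$ is the
area of the cell *opposite* the edge and $a, b$ are the perimeters of the
two cells *flanking* it; the Nagai–Honda force is its
gradient-of-an-energy counterpart with ideal areas and perimeters.

On the **macroscopic level** only the cell number density
$\rho = 1/V$ survives.  Mass conservation plus a Darcy closure
$v = -\mu \nabla p$ give the nonlinear transport equation

$$\frac{\partial \rho}{\partial t} = \mu \, \nabla \cdot (\rho \nabla p),$$

which needs a constitutive law $p(\rho)$ to close.  The package's core is
the *derivation of that law from the microscopic forces*: the discrete
model is read as a finite-volume discretization of the transport
equation on the Voronoi mesh of the cells, and matching the two velocity
expressions identifies the pressure.

## Geometry: the shape factor $\xi_d(J)$

The force laws see distances and perimeters; the macroscale only sees
$V$.  The missing geometry is supplied by idealizing each cell as a
regular polygon (2D) or polyhedron (3D) with $J$ neighbors, for which a
single factor $\xi_d(J)$, defined by $r = \xi_d(J)\,V^{1/d}$ (inradius to
volume), fixes everything:

```{r}
shape_relations(2, 6, 1)
xi_factor(2, c(3, 4, 5, 6)); xi_factor(2, Inf)
```

$\xi_1 = 1/2$ exactly; $\xi_2(J) = (J\tan(\pi/J))^{-1/2}$ increases from
the triangle to the circle limit $1/\sqrt\pi$; $\xi_3(J)$ follows from
the Platonic closed forms with the sphere limit $(3/4\pi)^{1/3}$.  For
$d = 3$ and a $J$ with no regular polyhedron (no regular 10-faced solid
exists, for example) the package interpolates piecewise-linearly in
$1/J$ through the Platonic values — a package choice, since no closed
form exists — and accepts an explicit override.  Defaults are $J = 2$
(forced) in 1D, $J = 6$ in 2D (dense tissues are near-hexagonal, and
this is the value the 2D experiments use) and $J = 12$ in 3D (the
kissing number of the sphere).

## The pressure laws

Matching the CBM force sum with the finite-volume form of the Darcy
velocity on the Voronoi mesh gives the interface pressure
$p_{ij} = -V_i\, g(r_{ij})/(\mu a_{ij})$ and, with the regular-shape
closure, the continuum law

$$p(V) = -\frac{J \xi_d}{d\,\mu}\, V^{1/d}\, g\!\left(2 \xi_d V^{1/d}\right),$$

implemented by `cbm_pressure()` (in 1D it collapses to
$p = -V g(V)/\mu$).  The same construction on the dual mesh for the
Weliky–Oster force gives `wo_pressure()`.  A power law
$p = K_\gamma \rho^\gamma$ ($K_\gamma > 0$, $\gamma > 1$), the isentropic
gas analogue, is included as a smooth well-posed reference law.  The
correspondence is invertible: `f_from_cbm()` turns a center-based force
into a vertex force function with the *same* macroscopic pressure, and
the package tests verify the round trip numerically.

Two derived quantities matter for the PDE:

* `dpdrho()` — the diffusion coefficient of the transport equation is
  $\mu\rho\,\partial p/\partial\rho$, evaluated analytically per law
  (with one-sided derivatives at the exponential force's cutoff
  discontinuity, using the interior branch at exactly $r = r_A$);
* `stability_thresholds()` — for a center-based law with a force cutoff,
  the coefficient *vanishes* below
  $\rho_{\text{vanish}} = (2\xi_d/r_A)^d$ (cells out of force range) and
  is *negative* in a band just above it, where the PDE is ill-posed.
  The sign-change density is found by bracketing and bisection of the
  analytic derivative to $10^{-10}$; for the reference exponential
  parameters ($\mu = 50$, $s = 1$, $c = 10$, $r_A = 1.5$) this gives
  0.901 and 0.667, and the bisection root is cross-checked in the tests
  against the closed-form quadratic root
  $10V^2 - 12V + 1 = 0$.  The second, very-high-density sign change is
  exposed only as a diagnostic attribute: it sits far outside the regime
  the models are meant for.

```{r}
glance(pressure_law_cbm(exp_force(), d = 1))
```

## Microscopic integration

Both models use forward Euler exactly as the macroscopic scheme does, so
micro/macro comparisons are not confounded by the integrator.  Design
choices the user should know:

* **Neighbor search.** CBM velocities sum over *all* pairs within
  $r_A$, found by a bucket-grid query, not just Voronoi neighbors; with
  the default parameters and near-equilibrium spacing the two sets
  coincide.
* **Boundaries.** Cells whose Voronoi region touches the domain wall
  (CBM) and wall vertices (VBM) are frozen, which keeps the total mass
  of the micro system constant — the discrete counterpart of the
  zero-flux boundary condition.
* **Tessellation refresh.** The CBM re-tessellates every step by default
  (`retessellate_every`); the tessellation is diagnostic for the CBM
  (densities), so coarser refresh rates only affect reporting, not the
  dynamics.
* **The VBM mesh is the state.** Polygons initialized from a Voronoi
  diagram are advected vertex-by-vertex with all velocities evaluated
  before any vertex moves.  Topological (T1/T2) rearrangements are not
  modelled; a step that would collapse an edge (below $10^{-6}$ of the
  initial mean edge length), invert a polygon or self-intersect is
  rejected with a suggestion to reduce `dt`.  Likewise, cocircular
  center sets (e.g. four centers on a circle) produce Voronoi vertices
  with more than three incident cells; such meshes are flagged
  degenerate and rejected by the vertex force routines rather than
  silently perturbed.
* **1D geometric conservation law.** `gcl_volume_update()` advances cell
  volumes by interface fluxes instead of re-tessellating; in 1D the
  midpoint interfaces move at exactly the mean of the neighbor
  velocities, so the two routes agree to round-off (a strong consistency
  test of the flux form).

## Macroscopic finite-volume solver

`fvm_step()` implements the standard conservative two-point flux scheme
with arithmetic-mean interface density $\tfrac12(\rho_i+\rho_j)$,
element-center pressures $p_i = p(1/\rho_i)$ and zero-flux boundary
faces; fluxes telescope, so total mass is conserved to round-off, which
the tests assert over $10^4$ steps at $10^{-10}$ relative.  Empty
elements use $p = 0$ and the mean-density face weight handles the
degenerate face; a step producing negative density is an error, not a
clipped value.  No upwinding or flux limiting is added: in the
negative-diffusion band the scheme oscillates, and reproducing those
oscillations (rather than suppressing them) is part of the package's
purpose.  A conservative timestep estimate
$\Delta t \le \omega_{\min}\ell_{\min} / (\mu \max|\rho\,p'(\rho)|\sum\sigma)$
is reported in the run manifest but deliberately not enforced.

The specialized 1D schemes exist because the 1D algebra simplifies:
`fvm_step_cbm_1d()` is algebraically identical to the generic step with
the 1D center-based law (the force scale and the Darcy mobility cancel;
the tests require agreement to $10^{-13}$).  `fvm_step_wo_1d()` is
different in kind: in 1D the Weliky–Oster force function makes
$V f(V) = \varsigma$ constant, so no pointwise pressure field exists,
and the usable discrete pressure $p_j = V_i f(V_j)/\mu$ depends on the
updating cell $i$.  The resulting scheme is *not* in conservative flux
form — its pairwise mass defect is
$\varsigma(V_i/V_j + V_j/V_i - 2) \ge 0$, second order in the density
contrasts — and the tests assert exactly that (a small, quadratically
shrinking drift) instead of pretending it conserves.

With the smooth power law, grid refinement on a smooth solution shows
the expected second-order spatial convergence (observed orders above
1.8 between three grids at $n = 40, 80, 160$ against an $n = 320$
reference).

## Synthetic initial conditions: what they emulate

The experiment generators are parameterized by density regimes, not by
point-by-point initial data:

* `ic_profile_1d()` places $N$ centers at the mass quantiles of a smooth
  cosine-bump density profile, so the tessellated per-cell density
  tracks the profile within 2% away from the walls.  The presets choose
  bump mass = $N - \rho_0 L$, so the background density is exactly the
  equilibrium value 1: 40 cells on $[0, 37]$ with a peak to
  $\rho \approx 1.6$ (repulsive regime, stable diffusion), and 40 cells
  on $[0, 47]$ with a depletion to $\rho = 0.5$, which straddles the
  unstable band $(0.667, 0.901)$.
* `ic_hex_2d()` builds a triangular lattice whose spacing is fixed by
  the outer density 1.15 ($h = \sqrt{2/(\sqrt3 \cdot 1.15)}$, about
  1755 cells on $[0,40]^2$), then compresses cells radially inside a
  disturbance radius with the smooth map
  $r \mapsto r(1 - a\cos^2(\pi r/2R))$, $a = 1 - 1/\sqrt{\text{factor}}$.
  The default factor 1.65 raises the central density to about 1.84,
  within the target central band $[1.11, 1.97]$ of this experiment
  design; mass displaced by the compression shows up as a shallow
  depletion annulus near the disturbance edge (which is why the central
  band extends below the outer density 1.15).  The density profile is
  monotone on the inner three quarters of the disturbance radius by
  construction.

What the generators deliberately do **not** model: cell division and
death, stochastic motility, heterogeneous cell types, and topological
rearrangements.  Passing tests therefore demonstrate that the
coarse-graining and the solvers are mutually consistent under the
stated mechanics — not that the mechanics describe any particular
tissue.

## The paired experiments

`run_paired_cbm_1d()`, `run_wo_1d()` and `run_paired_cbm_2d()` run both
levels from the same initial state: the micro model generates the
initial density samples, `micro_to_grid()` interpolates them to the
element centers (1D linearly; 2D piecewise-linearly on the Delaunay
triangulation recovered from the Voronoi dual), and both are advanced
with the same timestep.  The 2D comparison grid is the interior window
$[8, 32]^2$ of the $[0, 40]^2$ micro domain, so the frozen micro
boundary never contaminates the comparison.  Because the discrepancy
between the levels is a property of the regular-shape closure (largest
at density peaks, where real cells are least regular), the package's
checks are property-based: monotone relaxation on both levels and a
final $L_\infty$ gap below 10% of the initial bump amplitude in 1D;
region-averaged densities agreeing within 0.5% in 2D; oscillations
confined to the sub-0.901 band in the low-density run, with the micro
model oscillation-free.

Problem sizes were chosen to keep a full paired 2D run (1755 cells,
1800 steps, per-step re-tessellation) around two minutes on one core;
the 1D runs take seconds.

```{r, fig.alt = "Pressure and diffusion coefficient of the reference force law"}
law <- pressure_law_cbm(exp_force(), d = 1)
tab <- pressure_table(law, vmin = 0.5, vmax = 2, n = 300)
plot(tab$rho, tab$rho * law$mu * tab$dpdrho, type = "l", col = "red",
     xlab = expression(rho), ylab = "diffusion coefficient")
abline(h = 0, lty = 3); abline(v = c(0.667, 0.901), lty = 2)
```

## Numerical choices and tie-breaks

* Voronoi regions are closed by clipping against the rectangular domain
  (identical, for a rectangle, to mirroring the centers across each
  face), so the cells partition the domain exactly; the partition
  identity $\sum V_i = |\Omega|$ is asserted at $10^{-10}$ relative.
* Shared-edge lengths computed independently from each side are averaged
  to enforce $a_{ij} = a_{ji}$ exactly.
* Coincident-vertex identification in the dual mesh clusters at
  $10^{-9}$ of the domain scale (single linkage); duplicate *centers*
  are rejected at $10^{-12}$.
* The spacing of a requested macro grid is snapped to the nearest exact
  divisor of the domain extent (recorded in the grid's notes), keeping
  the comparison window exact rather than the nominal spacing.
* All simulations are deterministic; random numbers appear only in test
  fixtures and are always seeded.

## Limitations

The regular-shape closure degrades where cell geometry is far from
regular — at sharp density peaks and near ragged boundaries — which is
precisely where the micro and macro solutions are observed to differ
most.  The negative-diffusion band makes the center-based PDE ill-posed
at low density; the package reproduces the resulting persistent grid
oscillations and treats negative densities as errors rather than
regularizing them.  Proliferation source terms, 3D tessellation, hybrid
micro–macro coupling and non-local force kernels are out of scope.
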