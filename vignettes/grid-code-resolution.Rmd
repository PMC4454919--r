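---
title: "Lattices, sphere packings, and the resolution of grid-cell codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattices, sphere packings, and the resolution of grid-cell codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridfisher)
```

## The question

A neuron with a periodic tuning curve — a grid cell — fires near every
node of a lattice tiling the animal's environment.  A *module* of such
neurons shares one lattice and one radial tuning shape but scatters its
spatial phases across the lattice's unit cell, so that together the
cells cover space uniformly.  This package quantifies how well a
downstream observer can decode position from one such module, and how
that accuracy depends on the geometry of the lattice.  The answer it is
built to demonstrate: accuracy is proportional to the inverse volume of
the unit cell, so among geometries with the same node-to-node distance
the *densest sphere packing* gives the best code — hexagonal in the
plane, face-centered cubic (or any equally dense close stacking, such
as HCP) in three dimensions, and E8 in eight.

## Model and assumptions

Positions live in `R^D`.  A geometry is either a full-rank lattice
`L = { Σ k_α v_α }` or a layered sphere packing; both support a
nearest-node map `π` sending `x` to its offset from the closest node.
Cell `i` has phase `c_i` in the Voronoi cell `V₀` of the origin and
mean rate `f_max · Ω(‖π(x − c_i)‖)`.  Spike counts in a window `τ` are
independent Poisson across cells.  The assumptions that carry the
theory:

* **Radial tuning.** `Ω` depends only on distance to the nearest node.
* **Compact support.** `Ω(r) = 0` for `r ≥ θ₂`.  When `θ₂` is at most
  the packing radius (half the minimal node distance), each firing
  field sits strictly inside its cell, which is what makes the
  cross-geometry comparison exact.
* **Uniform phases.** Large-module averages assume phases uniform on
  `V₀`; the finite-`M` drivers sample them that way.
* **Independent noise.** Only the count distribution enters through a
  scalar Fisher factor `N(s)`; Poisson (`N(s) = 1/s`) is the shipped
  instance, and other count models can be plugged into
  `poisson_noise(fisher_factor = ...)`.

The shipped tuning shape is the bump
`Ω(r) = exp(θ₁/θ₂² − θ₁/(θ₂² − r²))` for `r < θ₂`: smooth everywhere,
identically zero beyond `θ₂`, value 1 at the node.  `θ₂` (units of the
node distance) is the field radius; `θ₁` (dimensionless) steepens the
flank as it decreases.

## From Fisher information to packing ratios

For a single cell the Fisher-information matrix at the origin is rank
one, `F(r)·uuᵀ`, with `u` the unit vector toward the phase and

\[ F(r) \;=\; (f_{max}\tau)^2\,\Omega'(r)^2\, N\!\big(f_{max}\tau\,\Omega(r)\big)
   \;\overset{\text{Poisson}}{=}\; f_{max}\tau\,\frac{\Omega'(r)^2}{\Omega(r)} . \]

A derivation note, because it is a classic trap: if one differentiates a
function of the *squared* radius, factors of `2x_α` appear and the trace
looks like `4r²(dΩ/d(r²))²/Ω`; expressed through the plain radial
derivative this is exactly `Ω′(r)²/Ω(r)`.  The package works in plain
radius throughout.  Two checks pin the convention down: `F` must carry
units of inverse squared length, and dilating the whole module by `λ`
must multiply the information by `λ⁻²` (`scale_fi()`; the suite tests
both at `λ = 1/2, 2`).

Summing `M` cells and letting phases be uniform on `V₀` gives the
per-neuron average

\[ \mathrm{tr}J_L \;=\; \frac{1}{\det L}\int_{V_0} F(\lVert c\rVert)\,dc
   \;=\; \frac{S_{D-1}}{\det L}\int_0^{\theta_2} F(r)\,r^{D-1}\,dr
   \qquad (\theta_2 \le R_{pack}), \]

where the second equality uses the compact support: the integrand
vanishes outside the in-ball, so the awkward cell-shaped domain
collapses to a 1-D radial integral *identical for every geometry*.  All
geometry dependence sits in `1/det L` — equivalently, in the packing
ratio `Δ(L) = vol(B_{R_{pack}})/det L` once node distances are fixed.
Denser packing, better code; the orderings `Δ(H) > Δ(Q)` and
`Δ(FCC) > Δ(BCC) > Δ(C)` translate directly into resolution orderings.

When `θ₂` exceeds the packing radius the field spills across the cell
boundary, the reduction to a radial integral fails, and which geometry
wins depends on the interplay of tuning shape and cell shape.
`average_fi()` then refuses the quadrature path and estimates the full
matrix by Voronoi Monte Carlo instead.

## Estimators and their numerics

`average_fi()` exposes three methods:

* `radial_quadrature` — adaptive quadrature (`stats::integrate`,
  relative tolerance `1e-8`) on `[0, θ₂(1 − 1e-10)]`.  The integrand is
  smooth and vanishes at both ends; the endpoint shave avoids the
  removable `0/0` at the support boundary.  Inside `Ω` itself,
  evaluations within `1e-12` of `θ₂` return the analytic limit 0, and
  the integrand masks points where `Ω` underflows below `1e-300`
  (there `Ω′²/Ω` is analytically 0 but floating point would produce
  `0 · Inf`).
* `voronoi_mc` — the mean of the rank-one matrices over uniform phases
  (default `2e6` points, a few seconds; standard error of the trace
  reported, seed recorded in the result).  Phases are drawn uniformly
  in the basis parallelepiped and reduced to the nearest node, a
  measure-preserving map onto the Voronoi cell.  The off-diagonal
  entries are *computed*, not assumed zero, so the isotropy of the
  average is a genuine property test rather than a construction.
* `population_fi()` — the exact finite sum for a concrete module; no
  integration at all.

Nearest-node reduction solves the basis system in reals, rounds, and
exhaustively checks an offset window — `{−1,0,1}^D` in 2D/3D, widened
to `{−2,…,2}^D` in higher dimension, where rounding against a skewed
basis can miss the true minimiser.  Ties on Voronoi boundaries (a
measure-zero set, so irrelevant to any integral) go deterministically
to the lexicographically smallest coefficient vector.  Shortest
vectors and kissing numbers come from an exact depth-first enumeration
on the Cholesky factor of the Gram matrix, pruned by the best length
found so far; a plain integer-box search over `k ∈ [−3, 3]^D` serves as
the independent oracle in the tests.  For layered packings the
nearest-center query reduces against the period lattice once per motif
layer.

## Design choices that were genuinely open

* **3D angle family.** `angle_lattice(phi, psi)` uses
  `v₁ = (1,0,0)`, `v₂ = (cos φ, sin φ, 0)`,
  `v₃ = (cos ψ, 0, sin ψ)`: three unit vectors with determinant
  `sin φ · sin ψ`, the determinant law the sweep is meant to exhibit.
  Other unit-vector liftings with the same determinant exist; any of
  them gives the same trace, so the simplest was chosen.  Angles are
  restricted to `[π/3, π/2]` — below `π/3` two nodes would come closer
  than the unit node distance.
* **Stacking coordinates.** Layers sit at the standard deep-hollow
  offsets `γ₀ = (0,0)`, `γ₁ = (1/2, 1/(2√3))`, `γ₂ = (1/2, −1/(2√3))`
  (times the diameter), with vertical spacing `d√(2/3)`; words are
  applied cyclically, and words with equal cyclic neighbours are
  rejected.  The `ABC` word reproduces the FCC lattice, but the package
  keeps `sphere_packing` and `grid_lattice` as distinct types and
  establishes their equality in tests, preserving the conceptual
  lattice-versus-packing distinction.
* **Unpaired comparisons.** `compare_modules()` draws phases
  independently per geometry and per realization (each from its own
  substream of the master seed, so runs are order-independent and
  reproducible).  Paired draws — same unit-cube variates pushed through
  both bases — are available via `paired = TRUE`; pairing roughly
  halves the crossover fraction, so the two modes answer different
  questions and the unpaired one is the default reading of independent
  realizations.
* **"Outperforms" is strict.** Ties (probability zero) count as not
  outperforming.

## What the generators emulate — and what they do not

The synthetic study conditions are those of the analysis the package
implements: bump tuning with `θ₁ = 1/4`, `θ₂ = 0.4`, peak rate and
window normalised to `f_max = τ = 1`, unit node-to-node distance,
modules of `M = 200` phases, and `5000` realizations for the
finite-module distributions.  The defaults of `average_fi()` use
`2e6` Monte-Carlo points (trace standard errors near 0.1 %); the test
suite uses `2e5` points where only 3-standard-error agreement is being
checked, and the large-`M` convergence check uses a single module of
`1e5` phases.  These sizes are desk scale: the whole suite runs in
well under a minute.

Passing tests therefore show that the *idealised* code behaves as the
theory says.  They do not speak to real grid cells, whose fields
deviate from perfect lattices near boundaries, vary in peak rate, show
correlated trial-to-trial noise, and are read out by biological
decoders rather than the Cramér–Rao bound.  Local field defects enter
the information only through a phase average, so mild incoherent
variability should not change the ranking — but that robustness is an
argument, not a computation performed here.

Two quantitative observations from the finite-module driver deserve
honesty.  With `M = 200` the per-realization trace has a coefficient of
variation near 10 % (2D) and 14 % (3D).  The hexagonal-vs-square
crossover fraction converges to about 17 % under unpaired draws (about
11 % paired).  In 3D the FCC and simple-cubic distributions overlap
enough that the cubic module wins roughly 5 % of unpaired realizations
at these parameters — the mean advantage of `√2` is large, but it is
not a sure thing realization by realization; a claim that the denser
lattice *always* wins at this module size is not supported by the
model.

## Known limitations

* Lattices are limited to the shipped families and dimensions up to 8;
  no LLL-style reduction is attempted, so `lattice()` with a very
  ill-conditioned custom basis may make the bounded reduction window
  insufficient (the shipped and angle-family bases are verified against
  brute force).
* Packings are restricted to layered close stackings, where Voronoi
  cells are congruent and a module phase density is well defined;
  general packings do not admit a meaningful module construction.
* Only count statistics within one window enter; there is no spike
  timing, no multi-module nesting, and no explicit decoder — the
  Fisher information is the resolution proxy throughout, so all
  statements are about the asymptotic regime in which efficient
  decoders attain it.
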