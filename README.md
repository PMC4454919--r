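# gridfisher

Spatial resolution of grid-cell population codes, measured by Fisher
information and ranked by sphere packing.

Grid cells fire whenever an animal is near any node of a lattice tiling
its environment — hexagonal in planar arenas.  `gridfisher` asks the
design question behind that observation: among all ways to arrange the
firing fields of a population of periodically tuned neurons in `D`
dimensions, which arrangement lets an ideal observer decode position
most accurately?  The package is aimed at computational neuroscientists
and anyone interested in lattice codes for continuous variables.

## The model

A *grid module* is an ensemble of `M` neurons sharing a radial tuning
shape `Ω` and a geometry `L` (a lattice, or a layered sphere packing
such as HCP), differing only in their spatial phases `c_i`, which sit in
the Voronoi cell `V₀` of the origin.  Cell `i` fires Poisson spikes in a
window `τ` with mean rate

    f_i(x) = f_max · Ω( ‖π_L(x − c_i)‖ ),

where `π_L` maps a point to its offset from the nearest node.  The
shipped tuning shape is the compactly supported bump

    Ω(r) = exp( θ₁/θ₂² − θ₁/(θ₂² − r²) )   for r < θ₂,  else 0,

with support radius `θ₂` (the field radius) and flank steepness `θ₁`.
For independent Poisson noise, a cell whose phase lies at distance `r`
from the decoded position contributes

    F(r) = f_max τ · Ω′(r)² / Ω(r)

to the trace of the population Fisher information, and for uniformly
distributed phases the average per-neuron trace reduces to a radial
integral over the in-ball of the cell:

    trJ_L = S_{D−1} / det(L) · ∫₀^{θ₂} F(r) r^{D−1} dr,    θ₂ ≤ R_pack.

The integral is the same for every geometry, so resolution is governed
by `1/det(L)` alone: *the densest packing wins*.  Writing `Δ(L)` for the
packing ratio (fraction of space covered by in-balls), the hexagonal
lattice beats the square lattice by `Δ(H)/Δ(Q) = 2/√3 ≈ 15.5 %` in 2D,
and in 3D the face-centered cubic lattice beats the simple cubic by
`√2 ≈ 41 %` and the body-centered cubic by `≈ 8.8 %` — with the
hexagonal close packing (HCP) and every other close stacking word
exactly tied with FCC.

## Worked example

```r
library(gridfisher)

om <- bump_shape(theta1 = 1/4, theta2 = 0.4)

# average Fisher-information trace per neuron, radial quadrature
average_fi(om, named_lattice("H"))$trace   # 33.0837
average_fi(om, named_lattice("Q"))$trace   # 28.65133
average_fi(om, named_lattice("FCC"))$trace # 23.9622
average_fi(om, named_lattice("C"))$trace   # 16.94384

# the ratios are pure determinant ratios:
33.0837 / 28.65133   # 1.154701 = 2/sqrt(3): the hexagonal advantage
23.9622 / 16.94384   # 1.414214 = sqrt(2):   the FCC advantage

# HCP (stacking word "AB") ties with FCC, by Voronoi Monte Carlo
average_fi(om, stacking_packing("AB"), method = "mc",
           mc_points = 2e6, seed = 42)$trace   # 23.93187 (se 0.031)

# finite modules fluctuate: M = 200 phases, 5000 realizations
cmp <- compare_modules(named_lattice("H"), named_lattice("Q"), om,
                       M = 200, n_realizations = 5000, seed = 1)
cmp$fraction_b_beats_a   # 0.1742: the square module wins ~17% of draws
```

The first block says a hexagonal module resolves position `2/√3` times
better than a square one with the same number of cells — exactly the
ratio of packing ratios.  The last line shows that at realistic module
sizes the ordering is statistical, not deterministic: a square-lattice
module outperforms a hexagonal one in roughly a sixth of random phase
draws, because with `M = 200` the per-realization trace has a
coefficient of variation of about 10 %.

Every result type has `tidy()`/`glance()` tidiers and an `autoplot()`
method; see `autoplot(cmp)` for the two overlaid realization
histograms.

A command-line front end with subcommands `packing-ratio`, `avg-fi`,
`sweep`, `compare` and `density-report` is installed at
`system.file("cli", "gridfisher.R", package = "gridfisher")`.

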