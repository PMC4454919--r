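Package: gridfisher
Title: Fisher Information and Sphere-Packing Analysis of Grid-Cell Lattice Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the spatial resolution of populations of
    grid cells whose periodic tuning curves are radial bump shapes tiled
    over arbitrary D-dimensional lattices or layered sphere packings.
    Provides constructors for named and angle-parameterised lattices
    (hexagonal, square, cubic, BCC, FCC, Z_D, E8) and for close-packed
    stackings of hexagonal layers (HCP, FCC and arbitrary stacking words),
    nearest-node reduction, packing radii and packing ratios, periodified
    tuning curves with independent Poisson spiking, and Fisher-information
    summaries per neuron and per module via radial quadrature, Voronoi
    Monte Carlo, or exact finite sums.  Seeded experiment drivers compare
    lattices at finite module size, sweep lattice angles, and tabulate
    packing-density advantages; results are tibbles with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
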