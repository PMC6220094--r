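Package: bifwave
Title: Coupled Endothelial and Smooth Muscle Cell Calcium Dynamics on
    Arterial Bifurcation Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates agonist-driven calcium signalling in the coupled
    endothelial (EC) and smooth muscle (SMC) cell layers of bifurcating
    arterial segments.  Builds parametric, non-planar bifurcation surface
    meshes obeying Murray's law, places axially aligned EC and
    circumferentially aligned SMC lattices on quadrilateral domains, and
    synthesizes luminal ATP concentration maps with high apex and low
    lateral-seam concentrations.  Single-cell dynamics combine an
    ATP/P2Y/G-protein/PLC IP3 production pathway with store-driven calcium
    exchange (CICR, SERCA, leak), membrane currents, and membrane potential;
    cells exchange calcium and membrane potential through electro-diffusive
    gap junctions and IP3 by Fickian diffusion, both homocellularly and
    across myoendothelial junctions.  Post-processing provides temporal
    averaging on the unwrapped surface, oscillation and wave-front metrics,
    and a frequency-sensitive zero-order-ultrasensitive protein
    phosphorylation model driven by the simulated calcium traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
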