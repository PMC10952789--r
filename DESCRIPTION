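Package: myowalk
Title: Monte Carlo Simulation of Diffusion Tensor Cardiovascular Magnetic
    Resonance with Permeable Membranes and Microvascular Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the diffusion tensor cardiovascular magnetic resonance
    (DT-CMR) signal from first principles. A random walk of water molecules is
    performed in a periodic, helix-angle-rotated substrate of extruded
    cardiomyocyte cross-sections with permeable sarcolemma and intercalated-disk
    membranes. Microvascular perfusion is modelled as spins advected at constant
    speed along capillary paths whose segment orientations follow a
    Dimroth-Watson axial distribution and whose lengths are Weibull distributed.
    Diffusion-encoding waveforms for stimulated-echo (STEAM), monopolar
    pulsed-gradient spin-echo (PGSE) and second-order motion-compensated
    spin-echo (MCSE) sequences are built as piecewise-linear effective
    gradients; diffusion and perfusion signals are mixed by a perfusion
    fraction and fitted to a mono-exponential tensor model with a configurable
    reference b-value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
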