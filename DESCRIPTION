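Package: dwconcept
Title: Density-Weighted Concentric Circle Trajectories for MR Spectroscopic Imaging
Version: 0.1.0
Authors@R:
    person("MRSI", "Tools", email = "mrsi-tools@example.org", role = c("aut", "cre"))
Description: Design and evaluation of concentric-circle spatial-spectral
    k-space trajectories for free-induction-decay magnetic resonance
    spectroscopic imaging (FID-MRSI). Implements the SNR-efficiency theory
    for density-weighted acquisition, the radius-map differential equation
    that places circle radii so the sampled k-space density equals a radial
    Hamming filter, minimum circle counts from the radial Nyquist criterion,
    hardware-feasible gradient waveforms with temporal interleaving and
    acoustic-resonance validation, a Kaiser-Bessel gridding reconstruction
    chain with modified Pipe-Menon density compensation directly onto the
    Hamming target, and an analytic simulation framework (phantoms,
    pseudo-replica SNR, localization experiments) that verifies densities,
    point spread functions, and SNR gains at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
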