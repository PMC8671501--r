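Package: hopta
Title: Surface-Hopping Dynamics and Transient-Absorption Simulation on Model
    Vibronic Hamiltonians
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation and analysis pipeline for the ultrafast
    photophysics of pyrimidine nucleosides. Analytic multi-state vibronic
    models with conical intersections stand in for on-the-fly electronic
    structure; trajectories are propagated with Tully's fewest-switches
    surface hopping (velocity-Verlet nuclei, interpolated time-derivative
    couplings, momentum rescaling along the nonadiabatic coupling vector and
    an energy-based decoherence correction), initial conditions are drawn
    from the ground-state Wigner distribution, and per-step energies and
    transition dipoles are turned into pump-probe transient-absorption maps
    (stimulated emission, excited-state absorption, hot-ground-state
    absorption). The analysis layer applies the protocol used on measured
    maps: IRF-convolved multi-exponential global fitting with
    decay-associated spectra, population lifetime fits, band-pass Fourier
    extraction of coherent oscillations, two-dimensional Fourier maps with
    node and phase analysis, excited-state normal-mode analysis, decay
    channel classification and ensemble barrier mapping.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
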