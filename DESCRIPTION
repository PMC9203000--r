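Package: tldos
Title: Two-Layer Diffuse Optical Spectroscopy: Forward Simulation and
    Homogeneous Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates broadband continuous-wave and frequency-domain
    diffuse reflectance from two-layered turbid media via photon diffusion
    theory, inverts the data with the semi-infinite homogeneous model that
    is standard in near-infrared tissue spectroscopy, and quantifies the
    partial-volume relationship between actual layered chromophore
    concentrations (oxy- and deoxyhemoglobin, water, lipid) and the
    effective homogeneous concentrations that such instruments report.
    Includes a sensitivity engine for dynamic cross-talk analysis and
    reproducible study drivers (baseline tables and one-parameter sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
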