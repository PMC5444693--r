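Package: pathdyn
Title: Simulation and Differential Visualization of Signaling-Network Kinetic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for exploring intervention regimes in kinetic models of
    cell-signaling networks. Imports reaction networks from SBML (Level 2/3 core subset),
    compiles them to ODE systems and integrates them under timed intervention regimes
    (drug boluses, concentration or kinetic-constant changes representing mutations),
    compares a Control and an Experiment regime over time with a white/red/blue
    difference encoding, computes force-directed layouts in the plane, in 3D, or
    constrained to a sphere, and renders per-time visual frames (node radius encoding
    concentration, edge thickness encoding reaction velocity) to PNG/JPEG sequences.
    Includes generators for small analytically tractable fixture networks and a
    subcommand command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    yaml,
    jsonlite,
    png,
    igraph,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
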