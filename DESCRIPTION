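Package: fiberheat
Title: Simulation of Metalized Electrospun-Fiber Microheaters and
    Thermally Triggered Drug Release
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling transparent microheaters made of random
    metalized fiber webs, as used in thermoresponsive transdermal drug
    delivery patches. Generates random fiber networks at a target geometric
    transmittance with pairwise overlap-area bookkeeping, builds the
    junction graph with length-weighted resistive edges and bus-bar or
    region electrodes, solves the DC resistor network by sparse nodal
    analysis (sheet resistance, per-segment Joule power), rasterizes
    spatial power-dissipation maps, runs ensemble sweeps of sheet
    resistance and percolation versus transmittance, and analyses
    voltammetric methylene-blue release kinetics (calibration line,
    current-to-mass conversion, release-rate estimation). Includes SPICE
    netlist export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
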