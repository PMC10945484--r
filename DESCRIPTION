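Package: dibkit
Title: Quantitative Analysis of Droplet Interface Bilayer, DSC and Raman
    Membrane Assays
Version: 0.1.0
Authors@R: person("dibkit", "maintainers", email = "dibkit@example.org",
    role = c("aut", "cre"))
Description: Tools for a three-assay model-membrane characterisation
    pipeline: inference of the osmotic water permeability coefficient
    (Pf) from shrinking droplet-interface-bilayer (DIB) droplet pairs,
    phase-transition thermodynamics (Tm, transition enthalpy, width at
    half height) from differential scanning calorimetry thermograms,
    and acyl-chain packing-order intensity ratios (I2930/2848,
    I2930/2890) from Raman C-H stretching spectra.  Includes seeded
    synthetic-data generators for all three assays (droplet-pair
    trajectories and images, endothermic thermograms, band spectra) so
    the full pipeline is testable without instrument data, plus CSV/JSON
    interchange and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
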