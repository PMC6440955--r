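Package: helixdx
Title: Backbone Dynamics of Transmembrane Helices from Amide Exchange and
    Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transmembrane-helix backbone dynamics from two
    complementary data sources. From amide deuterium/hydrogen exchange
    mass spectrometry it computes sequence-specific intrinsic (chemical)
    exchange rate constants with acid, base and water catalysis terms,
    fits residue-resolved exchange rates from electron-transfer-
    dissociation fragment ladders, and converts them into EX2
    Linderstroem-Lang hydrogen-bond opening free energies with
    Monte-Carlo error propagation. From molecular dynamics trajectories
    it measures intrahelical alpha and 3-10 hydrogen-bond occupancies,
    side-chain back-bonding, carbonyl packing scores, block-averaged
    backbone fluctuations, helix bend and swivel angles with hinge
    bending/twisting classification, and partial-least-squares
    functional mode analysis, and bridges the two worlds by predicting
    overall exchange kinetics from simulated hydrogen-bond occupancies.
    Synthetic-data generators with known ground truth make every stage
    testable without external measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    boot,
    minpack.lm,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
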