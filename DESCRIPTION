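Package: vheefocus
Title: Quadrupole-Focused Very High Energy Electron Beam Transport and
    Film Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying quadrupole-focused very high energy electron
    (VHEE) radiotherapy beams. Provides linear transfer-matrix beam optics
    with Twiss-parameter propagation and reconstruction from quadrupole
    scans, a condensed-history Monte Carlo for electron transport through
    magnet lattices with multiple Coulomb scattering (Highland formula),
    beampipe collimation and voxelised dose scoring in a water phantom,
    vacuum-optics focusing optimisation (final-quadrupole scans, polarity
    inversion, beampipe-radius studies), and radiochromic-film dosimetry
    (optical density, exponential dose calibration with fit statistics,
    dose-map maximum localisation and HWHM extraction). Synthetic-data
    generators with known ground truth make every stage testable without
    external measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
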