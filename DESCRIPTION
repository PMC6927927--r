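Package: ringmech
Title: Superelastic Nitinol Ring-Stent Bundle Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulator for full ring-stent wire bundles of the kind used in
    endovascular stent grafts. Implements a one-dimensional superelastic
    Nitinol constitutive model with tension-compression asymmetry, a
    geometrically nonlinear corotational 3-D beam finite-element core with
    fiber-discretized circular cross sections, circle-packing estimation of
    the bundle envelope, manufacturing pre-strain (wire-to-ring forming),
    a four-string saddle-pull structural-stiffness test, and radial
    compaction/deployment into a hyperelastic artery tube with pulsatile
    pressurization. Reports chronic outward force and per-cycle fiber
    strain extrema.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
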