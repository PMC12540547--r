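Package: thermascape
Title: Per-Tree Thermal Refugia for Birds from LiDAR Canopy Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps thermal refugia for arboreal birds at the scale of
    individual tree canopies in savanna landscapes. Segments tree crowns
    from a LiDAR-derived canopy height model (variable-window treetop
    detection and marker-based watershed delineation), derives a canopy
    density ratio per tree, downscales above-canopy weather to a
    within-canopy perch microclimate, solves steady-state heat budgets
    for a black-bulb operative temperature sensor and for endothermic
    birds, and scores every tree by the number of summer days on which a
    resting bird's body temperature is predicted to exceed a hyperthermia
    threshold under current and perturbed (end-century) climate forcing.
    Includes a seeded synthetic-data module (savanna stands with known
    per-tree ground truth, diurnal weather series, climate-scenario
    deltas, pseudo-observed black-bulb records) so the whole pipeline is
    testable without field data, plus the validation statistics used to
    compare predicted and observed daily-maximum distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
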