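Package: riceSSA
Title: Dynamic Stem-Sheath Angle Modelling for Rice Main-Stem Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the dynamics of the stem-sheath angle (SSA) of rice
    main-stem leaves as a function of thermal time, leaf rank, cultivar and
    plant nitrogen status, using a normalized logistic growth curve, a
    phyllochron power law, a piecewise-linear rank profile of maximum SSA
    and a critical-nitrogen dilution curve. Provides calibration routines
    that refit every model coefficient from observation tables, RRMSE-based
    validation against measured angles, a synthetic-data generator that
    emulates the tagged-plant measurement protocol, phytomer geometry
    helpers, and CSV/JSON input-output with a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
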