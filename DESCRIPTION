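Package: gaitmee
Title: Joint-Space Modelling of Metabolic Energy Expenditure During Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the instantaneous metabolic energy expenditure (MEE) rate
    of human walking in joint space, from joint angular velocities and actuator
    torques, using generalized activation-maintenance and
    shortening-lengthening heat coefficients that depend on subject mass, age,
    height and maximum knee extension torque. Provides instantaneous and
    phase-specific cost of transport, gait event detection and single/double
    support segmentation, bilateral stride synchronization, indirect
    calorimetry unit conversion, a constrained nonlinear least-squares
    estimator of the ten heat-coefficient weight parameters with
    thermodynamic inequality constraints, and a synthetic gait and metabolic
    data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
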