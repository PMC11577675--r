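Package: htosim
Title: Virtual Biplanar Open-Wedge High Tibial Osteotomy and Squat
    Kinematics Simulation
Version: 0.1.0
Authors@R:
    person("htosim", "maintainers", email = "htosim@example.org",
           role = c("aut", "cre"))
Description: Tools for in-silico medial open-wedge high tibial osteotomy
    (owHTO) on parametric lower-limb models. Generates synthetic cohorts
    calibrated to published anatomical index distributions (hip-knee-ankle
    angle, axial tibial tuberosity-trochlear groove distance,
    Insall-Salvati index), plans and executes biplanar osteotomies with
    ascending or descending tuberosity cuts at wedge heights of 6-12 mm,
    repositions the patella under a tendon-length constraint, runs a
    quasi-static squat simulation (5-100 degrees of knee flexion) of
    patellofemoral and tibiofemoral kinematics, and analyses the resulting
    flexion-sweep curves with root-mean-square errors, paired t-tests and
    linear mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
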