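Package: citsepi
Title: Controlled Interrupted Time Series Analysis of a Perinatal
    Antibiotic Policy Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the child-health impact of a hospital
    policy change from post-cord-clamping to pre-incision antibiotic
    prophylaxis at caesarean section, using a controlled interrupted
    time series (CITS) design with vaginal deliveries as the control
    series.  Provides a seeded synthetic mother-baby cohort generator
    emulating UK linked electronic health records, estimation of the
    national policy-uptake curve from a hospital survey, exposure
    assignment under a probabilistic (national uptake) or indicator
    (hospital change-year) regime, person-time expansion under the
    earliest-of censoring rule, Poisson rate-ratio and linear
    mean-difference CITS models with a rare-outcome guard, rate and
    proportion reporting on the events-per-1000-person-years scale, and
    a misclassification-aware power, bias, and coverage simulation
    framework.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
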