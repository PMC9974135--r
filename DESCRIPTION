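Package: glucopa
Title: Glucose-Insulin Regulation with Physical Activity in Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation, personalization and replay analysis of an
    exercise-extended two-compartment glucose-insulin model for type 1
    diabetes. The model couples a minimal-model core with subcutaneous
    insulin kinetics, meal carbohydrate absorption, and accelerometer-driven
    physical-activity processes: a prolonged rise in insulin sensitivity,
    insulin-independent increases in glucose uptake and production,
    glycogen-depletion effects during prolonged exercise, and a
    high-intensity production regime. Tools are provided to fit a small set
    of subject-specific parameters to continuous glucose monitoring data,
    to evaluate fits on held-out days, to compute profile-likelihood
    confidence intervals, and to replay recorded days under counterfactual
    meal, insulin and activity inputs. A synthetic-data generator emulates
    CGM, accelerometer and logbook streams with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
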