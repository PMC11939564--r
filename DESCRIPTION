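Package: radbp
Title: Contactless Blood-Pressure Estimation from Radar Micro-Vibrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for cuffless, non-contact blood-pressure
    estimation from continuous-wave radar chest micro-vibration recordings.
    Provides a seeded radar/arterial-pressure co-simulator, arctangent
    demodulation and zero-phase Butterworth preprocessing, beat detection and
    blood-pressure-anchored windowing, a cascaded regressor (1D residual
    network followed by a transformer sequence model with cross-coupled
    systolic/diastolic feature fusion), a robust Pseudo-Huber training regime,
    and the clinical validation suite (BHS grading, AAMI compliance,
    Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
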