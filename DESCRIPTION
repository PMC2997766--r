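Package: hemostress
Title: Noninvasive Hemodynamic Panels for Rest and Stress Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the complete noninvasive hemodynamic panel used in the
    stress echocardiography laboratory from basic rest and peak-stress
    measurements (heart rate, cuff blood pressure, left ventricular volumes,
    Doppler velocities): body surface area, stroke volume and cardiac output,
    mean arterial and end-systolic pressure, ventricular and arterial
    elastance indices and their ratio (ventricular-arterial coupling),
    systemic vascular resistance and arterial compliance, simplified-Bernoulli
    pulmonary pressures, two pulmonary vascular resistance estimators,
    pulmonary vascular capacitance, and diastolic-function metrics (E/e',
    estimated wedge pressure, diastolic mean filling rate). Pairs rest and
    peak panels into a calculated-results sheet with absolute and percent
    changes, classifies the force-frequency response and its critical heart
    rate, decomposes the stroke-volume response into end-diastolic and
    end-systolic contributions, and renders reports and trend plots. Includes
    seeded synthetic normal and dilated-cardiomyopathy training cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
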