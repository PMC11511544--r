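Package: vitalglove
Title: Smart-Glove Vital-Sign Monitoring, Smoothing and Alert Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing wearable smart-glove athlete-monitoring
    sessions: conversion of gyroscope angular velocity to linear speed via the
    rigid-body cross product about the elbow, moving-average and Gaussian
    smoothing of multichannel vital-sign streams (heart rate, SpO2, body and
    ambient temperature, speed), a threshold alert engine with a refractory
    period and the age-predicted maximum heart rate rule (220 - age), and
    quantification of how filtering reduces false alarms. Includes a seedable
    generator of three-phase (resting, walking, running) synthetic sessions,
    packaged reference tables, a Firebase-style key-path interchange format,
    and an end-to-end pipeline with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
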