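Package: mdltools
Title: Flight Segmentation, Light-Level Geolocation and Optimal Migration
    Models for Multi-Sensor Data Loggers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for miniature multi-sensor data loggers (MDLs)
    carried by migratory shorebirds. Segments 5-minute accelerometer activity
    scores into migratory flight bouts and stopovers, estimates positions from
    threshold light-level geolocation with Hill-Ekstrom or civil twilight
    sun-angle calibration, computes great-circle route metrics (haversine
    distance, detour index), and evaluates optimal-migration models predicting
    the number of flights for energy- and time-minimizing migrants. Includes a
    ground-truthed synthetic data generator emulating the MDL sampling routine
    so the whole pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
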