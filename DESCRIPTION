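Package: gaitfuse
Title: Multi-Modal Estimation of Propulsion from Pressure Insoles and IMUs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individualized estimation of the anterior-posterior ground
    reaction force (AP GRF) and clinical propulsion metrics during gait from
    wearable pressure-insole and inertial-measurement-unit (IMU) data.
    Provides a seeded multi-rate gait-session simulator (treadmill speed
    profiles, force-plate ground truth, 233-sensel insole frames, 21-channel
    IMU streams) for healthy and hemiparetic virtual subjects; a
    preprocessing chain (sensel zeroing, zero-phase Butterworth filtering,
    masked spatial Gaussian smoothing, gait-event detection, multi-rate clock
    alignment, area-interpolated 28x28 pressure maps, grouped min-max
    normalization, sequence construction); CNN, bidirectional-LSTM and fused
    CNN-LSTM estimators trained with Adam, including bout-based and ratio
    data splits and healthy-to-clinical transfer learning; and evaluation of
    stance-phase RMSE, peak propulsion, propulsion impulse, timing and
    propulsion symmetry against minimal-detectable-change thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Rcpp,
    jsonlite,
    data.table,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
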