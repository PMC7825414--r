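Package: lumbarload
Title: Wearable Sensor Estimation of Lumbar Moments During Manual Material Handling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates manual material handling trials with ground-truth L5/S1
    extension and lateral-bending moments from recursive Newton-Euler inverse
    dynamics, builds idealized and real-emulated wearable sensor channel sets
    (body-worn IMUs and pressure insoles), trains per-sample gradient-boosted
    tree estimators under leave-one-subject-out cross-validation, sweeps all
    sensor-location subsets, and reports accuracy (r-squared, RMSE, MAPE) and
    permutation-importance metrics for wearable low-back-load monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
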