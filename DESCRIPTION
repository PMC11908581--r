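Package: chromaqc
Title: Quality-Centric Evaluation of Chromatographic Data via Clustering and
    Per-Cluster Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes chromatographic peak-quality measurements
    (signal-to-noise ratio, replicate retention-time difference, peak
    skewness at half height, peak area) from raw time/intensity signals,
    groups compounds into quality-sensitive clusters with PCA and
    elbow-selected, silhouette-validated k-means, and validates the
    clusters by the per-cluster performance of grid-searched retention-time
    regressors. Ships a synthetic chromatogram simulator (exponentially
    modified Gaussian peaks over a linear baseline with Gaussian noise) so
    the whole pipeline is testable end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xgboost
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
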