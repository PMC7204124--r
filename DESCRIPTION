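Package: vdsmonitor
Title: Laryngeal Motion Monitoring and Phlegm-Stagnation Classification from Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects a moving laryngeal target in grayscale video by
    three-frame differencing, extracts its centroid-velocity sequence, and
    classifies the sequence as phlegm stagnation versus normal with a support
    vector machine whose kernel mixes a dynamic-time-warping sequence distance
    with a mean-velocity similarity term. Includes a synthetic video generator
    with ground-truth tracks, DTW-1NN and fixed-length-vector SVM baselines,
    and a sliding-window monitoring pipeline that raises alerts on positive
    classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
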