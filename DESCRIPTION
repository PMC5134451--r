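Package: gaitnorm
Title: Abnormal Gait Detection from 3D Skeleton Data with Discrete-Observation Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects abnormal human walking from 3D skeleton joint trajectories
    (e.g. Kinect v1 recordings at 30 fps). Each frame is summarised by seven
    lower-body joint angles, quantized into codewords with a seeded k-means
    codebook; walking is segmented into gait cycles at the local maxima of the
    exponentially smoothed foot-to-foot distance; a left-right (Bakis)
    discrete-observation hidden Markov model is trained on normal gait with
    multi-sequence Baum-Welch, and cycles whose forward-algorithm
    log-likelihood falls below a learned mean + lambda * sd threshold are
    flagged as abnormal. Includes a seeded kinematic simulator of normal and
    pathological walks (asymmetric, stiff-knee, shuffling, irregular) with
    ground truth, ROC/AUC/EER evaluation, model-selection grid search, broom
    style tidiers, ggplot2 plotting methods and a command-line interface.
License: MIT
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
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
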