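Package: infodyn
Title: Information Dynamics of Epoched Two-Site Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of directed information transfer and local
    information processing between two neural recording sites from epoched
    continuous signals (e.g. local field potentials). Implements
    delay-embedded state construction with Ragwitz-criterion parameter
    optimization, nearest-neighbour estimators for differential entropy
    (Kozachenko-Leonenko), active information storage and transfer entropy
    with information-transfer-delay reconstruction
    (Kraskov-Stoegbauer-Grassberger), Bayesian entropy estimation for
    discretized signals (Nemenman-Shafee-Bialek), surrogate-data and
    permutation-ANOVA inference, linear mixed-model comparison for nested
    epoch-within-recording designs, and a synthetic-data generator plus two
    simulation studies (band-pass filtering effects on delay reconstruction,
    and source-entropy effects on transfer entropy) for end-to-end
    validation without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    lme4,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
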