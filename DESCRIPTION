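Package: ambumetric
Title: Personalized Metric Learning for Daily Well-Being Estimation from
    Ambulatory Data
Version: 0.1.0
Authors@R:
    person("Ambumetric", "Developers", email = "ambumetric@example.org",
           role = c("aut", "cre"))
Description: Siamese-network metric learning for estimating daily well-being
    constructs (anxiety, stress, positive and negative affect) from multimodal
    ambulatory features. Learns an embedding in which within-participant
    pairwise distances mirror label proximity, jointly with a regression head,
    and supports trait-based personalization via feature augmentation and
    trait-cluster-specific models, fine-tuning with target-participant data,
    feed-forward and maximum-independence domain-adaptation baselines, and a
    participant-independent stratified cross-validation protocol with a
    person-identification privacy probe. Includes a synthetic cohort generator
    emulating the statistical structure of multimodal ambulatory studies so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
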