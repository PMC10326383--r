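Package: loopgan
Title: Multiple-Loop Adversarial Learning for Brain Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional (Pearson) and structural (volume-normalized
    streamline count) brain connectivity matrices, stacks modalities into
    multi-channel samples, and classifies two groups (abnormal vs healthy
    control) with a conditional Wasserstein GAN with gradient penalty and a
    patch-based critic. A multiple-loop-learning algorithm ranks real samples
    by the Euclidean distance between their critic patch maps and the
    generator's learned distribution, then trains a convolutional classifier
    incrementally on the easiest-to-learn half of each loop's batch. Includes
    symmetry-preserving cyclic augmentation of connectivity matrices, min-max
    scaling, ROC/AUC evaluation, and a synthetic two-class connectome
    generator so the full pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
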