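Package: pyrads
Title: Pyramidal Patch Deep-Feature Classification of Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for two-class radiograph classification with pyramidal
    patch-based deep feature generation, ReliefF feature weighting with
    iterative ranked-prefix selection, and cubic-kernel support vector
    machine evaluation under stratified k-fold cross-validation. Includes
    dataset loading with geometric augmentation and class balancing, a
    deterministic stub feature extractor for testing without pretrained
    network weights, and synthetic phantom radiograph generators with
    known class structure. Developed around automated flatfoot (pes
    planus) screening from weight-bearing lateral foot X-rays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
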