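Package: dissolvenet
Title: Deep Learning Prediction of Pharmaceutical Formulation Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts in-vitro properties of pharmaceutical formulations from
    tabular formulation descriptors with small fully-connected neural
    networks. Implements two pipelines: a PCA-reduced regression network for
    the disintegration time of oral fast disintegrating films (OFDF), and a
    multi-output network for 4-point cumulative dissolution profiles of
    sustained-release matrix tablets (SRMT) trained on data augmented by a
    Wasserstein GAN with weight clipping. Includes label-binned oversampling
    (ROS, SMOTE, ADASYN), a cumulative-release validity filter for generated
    profiles, a 2-D PCA mode-collapse diagnostic, pharma-specific evaluation
    metrics (within-10-second accuracy, the FDA f2 similarity factor), and
    seeded synthetic-data generators emulating both dataset structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
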