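Package: col6fl
Title: Federated Learning Benchmark for Collagen VI Immunofluorescence Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible benchmark for horizontal federated
    learning on collagen VI immunofluorescence images. Provides a procedural
    generator of labeled, patient-grouped fluorescence-matrix-like images for four
    pathogenic-mechanism classes (control, glycine substitution, pseudoexon
    insertion, exon skipping) across heterogeneous acquisition sites; the standard
    training-set augmentation pipeline (45-degree rotations, horizontal flips, HSV
    value scaling, resize and [0,1] normalization); deterministic texture-descriptor
    feature extraction with a linear softmax head; FedAvg federated training with
    single-node and pooled-centralized baselines; macro-F1 multiclass evaluation
    with confusion matrices and multi-trial mean/SD summaries; and an experiment
    orchestrator that reproduces the single-node-versus-federated comparison on
    synthetic two-site data with realistic size asymmetry and covariate shift.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
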