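Package: regscan
Title: Genome-Wide Prediction of Transcription-Initiating Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts promoters and enhancers directly from DNA sequence at
    genome scale. A coarse sliding-window scan model proposes candidate
    regions, a position-specific prediction model pinpoints transcription
    start sites at single-base resolution, and a third model assigns the
    strand of transcription. The classifiers are residual convolutional
    networks trained with an iterative hard-negative mining loop in which
    confident false positives from a genome scan are fed back into the
    negative training set, together with a random-shift augmentation that
    makes negatives impossible to memorize. Includes genome-level evaluation
    metrics (recall, precision, F1, false positives per correct call and per
    megabase with a 500 bp matching margin), a seeded synthetic-genome
    generator with planted promoter/enhancer grammars and confusable decoy
    loci, and a model-interpretation suite: PWM scanning, motif-replacement
    effects, window-substitution profiles, single-nucleotide mutation maps
    with k-means clustering, pairwise position-dependency maps, and a
    motif-pair independence test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
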