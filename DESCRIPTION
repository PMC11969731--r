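Package: nascentflow
Title: Nascent Transcriptome and RNA Pol II Interactome Analysis
Version: 0.1.0
Authors@R: person("Maintainer", "Nascentflow", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for metabolic RNA labeling (SLAM-seq)
    quantification and bait-normalized affinity-purification mass-spectrometry
    (AP-MS) interactome analysis. Counts T>C conversions per read, classifies
    labeled reads, applies RPMu normalization (TC reads over the library's
    non-TC read sum, times ten million), calls differentially labelled
    transcripts at fixed significance thresholds, stratifies effects by gene
    length and exon count, scores intronic polyadenylation events from
    per-intron coverage with a change-point ratio score, and implements the
    pseudo-floor / bait-normalize / t-test AP-MS workflow, with spike-in aware
    synthetic data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
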