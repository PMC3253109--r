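Package: qpcrkit
Title: Relative Quantification of RT-qPCR Data with Reference-Gene
    Validation and Normalizer Optimization
Version: 0.1.0
Authors@R: person("qpcrkit", "developers", role = c("aut", "cre"),
    email = "qpcrkit@example.org")
Description: A five-stage workflow for analysis of reverse-transcription
    quantitative PCR (RT-qPCR) threshold-cycle (Ct) data: estimation of
    per-gene PCR amplification efficiency from serial-dilution standard
    curves, ranking of candidate reference genes by the geNorm M-value
    stability statistic with stepwise exclusion, determination of the
    optimal number of reference genes via the pairwise-variation series
    V_n/n+1 computed from V_1/2 upward, efficiency-corrected delta-delta-Ct
    normalization against a multi-gene geometric-mean normalization factor,
    and expression-ratio statistics (pooled two-sample t-tests with
    Benjamini-Hochberg false-discovery-rate adjustment).  Includes a
    synthetic Ct-data generator with known ground truth for validation, and
    a command-line interface binding the stages into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
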