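Package: somaticQC
Title: Quality Control and Driver-Context Analysis for Somatic Variant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level quality control for tumor/reference sequencing
    studies with heterogeneous depth and purity: binomial detection-power
    modelling and callable-footprint computation, tumor-cellularity inference
    from allelic imbalance and somatic mutant-allele frequencies,
    clonality-aware somatic variant filtering, footprint-normalized mutation
    burden, mutational-signature refitting over the 96 trinucleotide contexts
    with a UV dipyrimidine-context fraction, focal copy-number event selection
    with allelic-imbalance corroboration, hotspot annotation, and
    Fisher/Benjamini-Hochberg mutational-overlap statistics. A synthetic
    tumor-cohort generator with known ground truth (cellularity, burden,
    signature mixtures, copy-number events, subtypes) drives end-to-end
    testing without access to controlled raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
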