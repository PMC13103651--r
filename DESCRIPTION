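Package: fctarget
Title: Seed-Based Functional Connectivity Mapping and Stimulation Target
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for thalamic seed-based resting-state functional
    connectivity (FC) analysis oriented toward non-invasive brain
    stimulation targeting: confound regression and motion censoring of
    BOLD time series, Pearson/Fisher-z seed FC maps, normative map
    averaging, volume-to-surface projection, surface peak detection with
    geodesic sphere regions of interest, a distance-decay surrogate for
    coil-induced electric fields with top-fraction cortical masking, and
    the accompanying group-comparison and symptom-correlation statistics.
    Includes a synthetic-cohort generator with planted connectivity and
    symptom-coupling structure so that every stage can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    RNifti,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
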