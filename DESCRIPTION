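Package: emgait
Title: Gait-Cycle EMG Analysis Under Transcutaneous Spinal Cord Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel surface electromyography (EMG)
    recorded during slow overground or exoskeleton-assisted walking while
    transcutaneous spinal cord stimulation (tSCS) is applied. Implements an
    artifact-robust preprocessing chain (zero-phase Butterworth band-pass,
    power-line notch, a pole-zero comb filter that places unit-circle zeros at
    the stimulation frequency and its harmonics, median smoothing, and
    cadence-adjusted linear-envelope extraction), gait-cycle segmentation by
    subsequence dynamic time warping of a data-derived envelope template,
    per-cycle root-mean-square and integrated-EMG amplitude metrics, and
    Wilcoxon rank-sum comparison of pre- versus post-stimulation walking
    blocks with percent-change summary tables. A ground-truthed synthetic
    gait-EMG simulator (burst-modulated band-limited noise, line interference,
    biphasic stimulation pulse trains, motion transients, injectable
    amplitude effects) supports validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
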