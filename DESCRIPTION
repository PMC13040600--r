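Package: emotraj
Title: Emotional Memory Trajectories from Multi-Session EEG, Sleep, and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how emotion-specific neural representations and
    emotional-memory behavior evolve across post-encoding, post-sleep, and
    7-day delayed sessions. Provides a synthetic multi-session ERP/hypnogram/
    behavior generator, wake-EEG preprocessing (FIR band-pass and notch
    filtering, resampling, common-average re-referencing, baseline correction,
    moving-window peak-to-peak artifact rejection), per-timepoint linear-SVM
    emotion decoding with temporal generalization across sessions,
    cluster-based permutation inference on time-time accuracy maps, sleep
    macrostructure metrics (TIB, TST, SOL, WASO, SE, stage minutes and
    percentages, arousal index, SWS x REM composite) from hypnograms, and
    correlation-level statistics (Spearman with Benjamini-Hochberg FDR,
    Fisher r-to-z comparison with Cohen's q, Huber robust regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
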