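Package: songCalcium
Title: Transition-Triggered Calcium Analysis of Drosophila Courtship Song
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for aligning Drosophila courtship-song annotations with
    neural calcium imaging. Converts classifier-style song probability
    tracks (pulse, sine, ambient, others, flight on a 1.6-ms grid) into
    smoothed labels, merged pulse trains, imaging-frame event flags and
    typed song-state transitions; computes dF/F, transition-triggered
    calcium statistics, a ROC-based song-type preference index with
    permutation nulls, voxel-wise preference maps with trial-shuffle
    significance, behavioral state-transition probabilities, and
    synapse-count connectivity summaries. A synthetic-data module
    generates song-state sequences, probability tracks, calcium traces,
    voxel movies and toy connectomes with the statistical structure the
    analysis assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
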