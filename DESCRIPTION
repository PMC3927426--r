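Package: songgate
Title: Closed-Loop Auditory Feedback Simulation and Song-System Physiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying auditory feedback processing in the songbird
    vocal motor system. Implements a discrete-time simulation of closed-loop
    distorted auditory feedback (DAF) experiments in singing zebra finches:
    frame-wise multitaper acoustic features (amplitude, spectral centroid,
    Wiener entropy, frequency modulation, cepstral pitch), amplitude-threshold
    sound-event detection, Gaussian-kernel support-vector-machine syllable
    classification, persistence-based target-syllable triggering with
    randomized hit/catch assignment and contingent escape rules. Companion
    analyses cover intracellular membrane-potential recordings (median-filter
    despiking, spike detection, baseline-subtracted hit-minus-catch membrane
    potential differences with windowed tests, depolarizing-PSP onset
    detection and k-means clustering, event-triggered PSP rate
    correlograms), playback-evoked auditory response statistics (two-stage
    Mann-Whitney / Ansari-Bradley procedure with response indices),
    dendritic-spine size-index and stability metrics from longitudinal 3D
    fluorescence stacks, and song-degradation onset detection from syllable
    Wiener entropy and entropy variance. Synthetic-data generators with
    known ground truth (song audio, membrane traces, trial sets, spine
    stacks) make every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    signal,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
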