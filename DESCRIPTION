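Package: meamod
Title: Spike-Train Analysis of Modular Neuronal Networks on Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing multi-electrode array (MEA) recordings from
    engineered modular neuronal cultures. Provides threshold-based spike
    detection from extracellular traces, binned firing-rate histograms with
    Gaussian smoothing, Pearson correlation matrices and intra-/inter-network
    correlation summaries, burst and synchronized-event detection with
    association degree and propagation-direction labelling, quantification of
    firing-rate suppression under targeted neuromodulation including a
    network-to-network influence statistic with exact Mann-Whitney testing,
    peri-stimulus time histograms for electrically evoked responses, and a
    seeded point-process simulator of modular bursting networks with exported
    ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
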