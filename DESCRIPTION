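Package: riftbci
Title: Simulation and Decoding for a Rapid-Invisible-Frequency-Tagging Brain-Computer Interface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully simulatable closed-loop brain-computer interface based on
    rapid invisible frequency tagging (RIFT). Generates flicker stimulus
    sequences at high tagging frequencies (56/60 Hz under a 1440 Hz frame
    clock), synthesises MEG-like recordings in which steady-state visual
    evoked responses are modulated by covert spatial attention, streams the
    data through a one-second ring buffer updated every 100 ms, decodes the
    attended side online from fourteen spectral-power features with a linear
    support vector machine, and drives a headless pong game from the decoder
    output. An offline analysis suite provides band-pass/notch filtering,
    epoching, Hanning-tapered time-frequency decomposition, spectral
    signal-to-noise ratios, information transfer rates, sliding-window power,
    cluster-based permutation statistics, and eye-movement confound checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
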