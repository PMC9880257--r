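Package: cionaphase
Title: Burst Detection, Phase Locking and Kinematics for Bilateral
    Motor-Neuron Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the development of bilateral motor-neuron activity
    from dual-channel calcium-imaging recordings of the Ciona motor ganglion.
    Provides burst detection on dF/F traces via Savitzky-Golay denoised
    derivatives, cycle-anchored circular phase assignment of left-channel
    bursts to the right-channel rhythm with Rayleigh uniformity testing,
    a rule-based seven-phase classifier of bilateral synchrony, three-point
    midline curvature and tail-bending kinematics with bout segmentation,
    and cohort-level laterality and photostimulation-response statistics.
    A synthetic-data module generates two-channel burst-oscillator traces,
    tail trajectories and cohort tables with known ground truth so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
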