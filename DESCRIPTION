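Package: DrowsyFusion
Title: Multimodal Driver Drowsiness Detection with Fuzzy Sensor Fusion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects driver drowsiness from multiple physiological and video
    channels and fuses the evidence with a Mamdani fuzzy inference system.
    Implements the eye-aspect-ratio (EAR) metric over six eye-contour
    landmarks with threshold segmentation of closed-eye intervals and blink
    statistics; matched-filter detection of S1/S2 pulse types on three
    electrooculography (EOG) channels with blink identification by the
    per-channel pulse signature; Welch power-spectral-density analysis of
    EEG epochs with delta/theta/alpha/beta band powers and an alpha-peak
    drowsiness criterion in the 10-12 Hz domain; feed-forward (2601-10-2)
    and stacked-autoencoder neural classifiers of 51x51 grayscale eye
    images; and centroid-defuzzified fuzzy fusion of the three channel
    scores into drowsy/alert decisions over sliding windows. Seeded
    synthetic generators for every modality make the full pipeline testable
    without sensor recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
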