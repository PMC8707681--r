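Package: icpwave
Title: Intracranial Pressure Pulse Waveform Morphology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the morphology of intracranial pressure
    (ICP) pulse waveforms from invasive and noninvasive (cranial
    micro-deformation) recordings. Segments cardiac pulses synchronized to
    the arterial blood pressure channel, excludes artifact beats, computes
    per-minute ensemble-averaged pulses, and extracts the P1/P2 landmarks,
    P2/P1 amplitude ratio and normalized time-to-peak. Includes a synthetic
    paired-signal generator emulating 10-minute monitoring sessions with a
    60-second jugular-compression plateau wave, and a validation layer with
    Bland-Altman limits of agreement, bootstrapped Pearson correlation, and
    ROC analysis of P2/P1 cut-offs for intracranial hypertension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
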