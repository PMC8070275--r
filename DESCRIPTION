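Package: pleurasound
Title: Acoustic Detection of Pneumothorax and Hemothorax from Breath Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting pleural air (pneumothorax)
    and fluid (hemothorax) accumulation from dual digital-stethoscope breath
    sound recordings. Provides a synthetic study generator emulating a
    mechanically ventilated porcine auscultation protocol, band-pass
    preprocessing and acoustic intensity/feature extraction, a weighted
    k-nearest-neighbour detector whose parameters are evolved by a
    multi-objective (Pareto) genetic algorithm, leave-one-out
    cross-validation, and permutation-based overfitting diagnostics.
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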