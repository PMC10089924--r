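Package: astrostate
Title: Hemodynamic Correction and Arousal-State Analytics for
    Astrocyte-Norepinephrine Imaging Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multimodal cortical arousal recordings:
    removal of multiplicative hemodynamic attenuation from fluorescent
    norepinephrine-sensor pixel movies via an iteratively refined vascular
    reference, wheel-speed and pupillometry processing, astrocyte calcium
    event filtering and event-triggered analytics, multitaper spectral
    estimation of local field potentials with median-normalized
    event-triggered spectrograms, arousal principal-component extraction
    from neuronal populations, and hierarchical and paired bootstrap
    resampling statistics. Includes a synthetic-session generator with
    full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
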