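Package: dyadsync
Title: Inter-Brain Synchrony Analysis for Dyadic fNIRS Hyperscanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing mother-child functional near-infrared
    spectroscopy (fNIRS) hyperscanning experiments. Implements the full chain
    from raw two-wavelength intensity to inter-brain synchrony (IBS):
    channel quality control (coefficient of variation, scalp coupling index),
    optical-density conversion, motion-artifact correction (temporal
    derivative distribution repair and wavelet filtering), the modified
    Beer-Lambert law, short-separation regression, Morlet wavelet transform
    coherence with permutation-based selection of task-related frequency
    bins, Fisher-z IBS statistics, child-language metrics (MLU, TNW, WPS,
    CPS) from CHAT-style transcripts, and the group comparison / FDR /
    Kendall-correlation statistical stage. A synthetic-dyad generator with
    known ground truth (coupling band and strength, physiological noise,
    motion artifacts, scalp component, latent verbal ability) makes every
    stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
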