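Package: jetsaxs
Title: Form-Factor Recovery from Liquid-Jet XFEL Small-Angle Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduction and analysis of serial small-angle X-ray scattering
    data collected with megahertz pulse trains on a liquid-jet free-electron
    laser instrument. Covers photonization of detector frames, density-based
    rejection of jet-flare and droplet-debris frames, pulse-intensity
    normalization, frame averaging with per-cell bad-pixel bookkeeping,
    azimuthal integration with Poisson errors, elution-trace construction
    with flanking-buffer subtraction, and downstream Guinier, pair-distance
    distribution and chi-square analysis. Includes a synthetic run simulator
    with ground truth so every stage can be validated without beamtime data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
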