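Package: spatial2dms
Title: Trap-Free Two-Dimensional Mass Spectrometry by Spatial Fragmentation Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and processing chain for two-dimensional mass
    spectrometry (2DMS) performed without an ion trap. Precursor ions are
    dispersed spatially by m/z -- either by a low-voltage side kick in a
    time-of-flight (TOF) pusher region followed by an incremented delay, or
    by an electric-sector deflection pulse of stepped duration -- and
    photofragmented by a spatially periodic (dual-slit) light pattern, so
    that each precursor's fragment intensity is modulated at a frequency
    characteristic of its m/z. The package provides idealized uniform-field
    ion kinematics, fringe-pattern evaluation, deterministic and stochastic
    scan engines producing transient cubes and per-scan event logs, Fourier
    processing with FWHM resolving-power measurement, the f = D/sqrt(m/z)
    frequency-to-precursor calibration, assembly of 2D precursor-by-fragment
    maps, a synthetic-mixture generator, file I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
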