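Package: frahm
Title: Coupled Reed-Bank Models of Cochlear Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates banks of elastically coupled, damped, passive harmonic
    oscillators driven in parallel by a sinusoidal force -- the vibrating-reed
    (Frahm) frequency meter historically used as an analogue model of the
    cochlea.  Provides a time-domain integrator with a compiled right-hand
    side, an exact frequency-domain phasor solver, bank builders (the 21-reed
    Wilson bank, Greenwood-map and linear-spacing banks), and a measurement
    toolkit: steady-state amplitude and phase profiles, travelling-wave
    waterfalls, ripple and secondary-peak statistics, attenuation slopes,
    impulse-response spectra, and frequency-plateau clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
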