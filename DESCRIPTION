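Package: uwoce
Title: Ultra-Wideband Optical Coherence Elastography Simulation and Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and analysis stack for swept-source optical
    coherence elastography (OCE) at vibration frequencies far above the
    A-line rate. Provides an interferogram simulator with vibrating
    scatterers, sweep-period timing jitter and detector noise; a general
    anti-aliasing sideband demodulation algorithm that recovers depth-resolved
    complex vibration amplitudes with in-situ stimulus-phase jitter
    correction; closed-form sensitivity and phase-noise budgets; surface
    wavefield analysis (spatial spectra, Rayleigh/supershear mode picking,
    analytic near-field surface-wave fitting); and elastodynamic inversion
    from dispersion curves to complex shear moduli, Lamb plate modes, and
    depth-resolved stiffness profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
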