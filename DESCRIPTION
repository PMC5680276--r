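Package: flagbeat
Title: Flagellar Beat Harmonics, Rotation Analysis and Active Filament
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the planar beat of tethered sperm flagella
    from tracked midline coordinates: curvature kymographs, principal-component
    beat modes with a random-curvature significance null, time-resolved
    fundamental and second-harmonic amplitude and phase from a windowed
    Fourier spectrogram, and the correlation between second-harmonic intensity
    and cell rotation velocity.  Includes resistive-force-theory closed forms
    for the rotation velocity driven by the second harmonic or by intrinsic
    curvature together with a numerical quadrature oracle, an overdamped
    inextensible active-filament simulator driven by two-harmonic bending
    torques (tethered and free-swimming modes, power profiles), a synthetic
    data generator for ground-truth waveforms and rendered dark-field-like
    image stacks, and a midline tracker for such stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
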