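Package: rastr
Title: Membrane Nanotube Signal Subtraction and Particle Recovery for
    Cryo-EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the RASTR approach (reconstruction of average
    subtracted tubular regions) for single-particle cryo-EM of specimens
    decorated on lipid nanotubes: autocorrelation-based in-plane alignment
    of tube segments, azimuthal-average reconstruction by direct Fourier
    inversion with randomized spin angles, axial smoothing, projection and
    least-squares subtraction of the tube signal, followed by
    template-based and template-free (picking-by-classification) particle
    recovery with cross-correlation duplicate elimination. Includes a
    synthetic decorated-tube simulator providing ground truth for every
    stage, MRC2014 and STAR-style file I/O, and a command-line pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
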