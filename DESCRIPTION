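Package: nutkin
Title: Kinematics of Nutation in Growing Plant Organs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and measurement of circumnutation kinematics in an
    elongating plant organ (a compound-leaf rachis). Implements a kinematic
    growth model in which bending is driven by a propagating, spatially
    localized differential-elongation pattern; orthogonal camera projection
    and the apparent elongation-rate field it induces; a synthetic time-lapse
    data generator with known ground truth (curvature and elongation
    kymographs, fluorescent node-marker tracks, speckle-textured frames);
    the measurement chain (midline extraction, circle-fit curvature, node
    tracking, segment and image-correlation elongation, Hilbert envelopes,
    apex-frame time-averaged profiles); continuous wavelet time-frequency
    analysis with the second-order complex-Gaussian wavelet; and model
    fitting including a local-contraction test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
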