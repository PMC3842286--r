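Package: plumekin
Title: Particle Image Velocimetry and Kinematics of Expiratory Plumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the kinematics of particle clouds expelled
    by sneezing and coughing, reconstructed from high-speed grayscale video.
    Provides a synthetic plume generator with ground-truth trajectories, PIV
    (particle image velocimetry) tracking by zero-normalized cross-correlation
    over 21x21 pixel interrogation windows with three-point Gaussian subpixel
    peak interpolation and successive-abandonment vector validation,
    front-line (distal margin) velocity extraction with Stokes settling-based
    exclusion of large fast-falling droplets, exponential velocity-decay model
    fitting Vh(t) = A*exp(-k*t) + c, and closed-form estimation of
    momentum-loss time and maximum direct reach.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
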