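Package: retinasim
Title: Scene Enhancement and Degenerate-Retina Simulation for Low Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image enhancement algorithms for people with retinal
    degenerative disorders (age-related macular degeneration, retinitis
    pigmentosa), together with a computational model of the degenerate
    retina used to evaluate them. Implements the TRON (Tinted Reduced
    Outlined Nature) gradient-weighting enhancement, image cartoonization
    with soft luminance quantization, and edge overlaying, all built on
    Perona-Malik anisotropic diffusion and a four-direction multi-scale
    gradient operator. The retina model simulates foveated space-variant
    blur, color-opponent centre-surround (difference-of-Gaussians)
    processing, gradient-domain Poisson reconstruction of the cortical
    image, and parametric scotomata with photoreceptor loss. Evaluation
    utilities cover an extracted-edge percentage metric, Pelli-Robson
    style contrast-sensitivity stimuli, a face-detection degeneration
    sweep, and a frame-difference motion metric, plus synthetic fixture
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    png,
    stats,
    utils,
    yaml
Suggests:
    jpeg,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
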