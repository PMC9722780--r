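Package: rlci
Title: Response-Locked Classification Images for Cued Contrast Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for a Posner-cued contrast
    detection task in dynamic one-dimensional noise. Implements the
    stimulus generator (two 16-bar Gaussian noise fields with a ramping
    central target and a probabilistic spatial cue), a model observer that
    filters the stimulus with a separable difference-of-Gaussians by
    biphasic spatiotemporal filter, amplifies the cued field by an
    attentional gain, and accumulates the left-right evidence difference
    in a noisy leaky integrator to a decision boundary; reaction-time
    analyses with harmonic means in cue-onset epochs; response-locked
    classification images and center/surround impact curves; and model
    fitting by RMS error on impact curves with common random numbers,
    including a parameter-recovery harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
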