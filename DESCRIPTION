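Package: nsnn
Title: Noisy Spiking Neural Networks and Noise-Driven Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of noisy spiking neural networks built
    from leaky integrate-and-fire neurons with escape-noise (probabilistic)
    firing. Provides the noise-driven three-factor learning rule and its exact
    correspondence with surrogate-gradient learning, a brute-force enumeration
    oracle and an unbiased local-marginalization gradient estimator for
    validation, Euler-Maruyama simulation of the membrane drift-diffusion
    dynamics with sample Lyapunov exponent estimation, perturbation operators
    for robustness studies (FGSM, direct-optimization attack, event dropping,
    spike-state flips), trial-to-trial variability analytics (Fano factor,
    prediction similarity), a postsynaptic-potential-kernel maximum mean
    discrepancy loss for spike-train fitting, and seeded generators for all
    synthetic inputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
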