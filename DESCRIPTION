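Package: foamimpact
Title: Falling-Weight Impact Testing of Protective Foam Mats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of falling-weight impact tests on layered
    cross-linked polyethylene foam mats used to protect athletes during strike
    force measurements. Provides a physics-based simulator of a rigid impactor
    dropped onto an elastoplastic foam specimen (densification, hysteresis,
    repetition degradation, specimen variability, sensor noise), segmentation
    of displacement-force traces into loading and unloading portions, energy
    decomposition into elastic and plastic parts, estimation of the undamped
    force by exponential extrapolation to zero displacement, per-layer
    zero-intercept transfer functions relating measured to undamped force, and
    repeated-loading statistics (repeated-measures ANOVA with one-sided post
    hoc paired t tests on the force reached at a reference absorbed energy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
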