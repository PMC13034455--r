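Package: photokin
Title: Photokinetic Modelling of Dark States in Fluorescent Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing the photokinetics of
    fluorescent-protein dark states. Implements a three-state (ground,
    excited, dark) rate-equation model with irreversible photobleaching from
    the bright and dark manifolds, stiff and reduced (rapid-equilibrium)
    integrators over arbitrary illumination waveforms (continuous,
    rectangular pulse pairs, Gaussian pulse trains), closed-form expressions
    for the sub-millisecond dark-state-conversion decay and the slow
    photobleaching rate, a seeded synthetic-trace generator with shot and
    detector noise, and the full curve-fitting pipeline used to extract
    dark-state conversion amplitudes and time constants, ground-state
    recovery times, and globally shared photobleaching time constants from
    fluorescence time traces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
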