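Package: prepjump
Title: Preparatory and Movement Subspace Analysis of Target-Jump Reaching Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing motor-cortical population activity recorded
    during delayed reaches with occasional last-moment target jumps. Provides a
    validated session container with JSON serialization, a synthetic-session
    generator with exported latent ground truth (orthogonal preparatory,
    movement and trigger dimensions driving Poisson spiking), Gaussian-kernel
    firing-rate estimation with soft normalization, movement-onset detection,
    psychometric sigmoid fits of initial reach angle against jump-to-onset
    latency, a linear support-vector decoder of movement initiation whose
    zero crossing defines a single-trial neural trigger event, leave-one-out
    cross-validated prediction of jump behaviour, a trace-ratio optimizer that
    identifies orthogonal preparatory and movement subspaces in the trigger
    null-space, cross-condition variance time courses, and subspace distance
    analyses of target-jump responses with rank-sum tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
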