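Package: chargetune
Title: One-Shot Fine-Tuning of Molecular Mechanics Charge Models by
    Zwanzig Reweighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Fine-tunes the electrostatic parameters of a pretrained
    molecular mechanics charge model against experimental free energies
    without re-running molecular dynamics. Atom embedding vectors are
    projected onto a truncated principal-component basis, low-rank linear
    perturbations are applied to per-atom electronegativity and hardness,
    partial charges are regenerated by charge equilibration (QEq), and
    perturbed free energies are obtained by Zwanzig (exponential)
    reweighting of stored per-frame electrostatic potentials.
    Optimization of the perturbation parameters uses a pseudo-Huber data
    loss with effective-sample-size (ESS) regularization and ESS-monitored
    early stopping under a quasi-Newton (BFGS) scheme. Includes an
    ESS-threshold bootstrap calibration, accuracy evaluation with
    Cramer-von Mises distribution-shift statistics, and a synthetic
    Gaussian linear-response data generator with closed-form free-energy
    oracles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
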