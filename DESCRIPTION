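Package: micromotion
Title: Motion Analysis and In-Silico Replication for Enzyme-Powered Micromotors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-particle motion analysis for catalytically self-propelled
    microspheres: time-averaged mean-squared-displacement (MSD) curves,
    propulsive-regime fits of speed and translational diffusion
    (MSD(t) = 4*Dt*t + v^2*t^2), and Stokes-Einstein rotational scales that
    define the fit window. Includes a kinetics-coupled active-Brownian-particle
    simulator (Langevin dynamics with competitive and substrate inhibition
    driving the propulsion speed), a microscopy-style frame renderer, spot
    detection and track linking, and pipeline helpers for dose-response sweeps
    and speed-activity correlation, so the whole inference chain can be
    exercised on synthetic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
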