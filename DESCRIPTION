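Package: colonysim
Title: Hybrid Agent-Based and Reaction-Diffusion Simulation of Bacterial Colony Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the development of a bacterial colony on an agar surface with a
    (1+1)-dimensional hybrid model: rod-shaped cells grow, divide and move under
    overdamped contact mechanics while glucose, oxygen and acetate obey
    reaction-diffusion dynamics across the agar and colony regions. Cell growth follows
    Monod kinetics for three metabolic modes (aerobic and anaerobic growth on glucose,
    aerobic growth on acetate) with a maintenance-energy requirement; cells whose carbon
    uptake falls below the maintenance flux accumulate starvation time and die at
    mode-specific exponential rates. The package also implements the colony morphometry
    observables used to characterise such colonies (cross-sectional profiles, disk-stack
    volume, peripheral monolayer width, flux partitioning, growing fractions) and an
    exponential viability-decay fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
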