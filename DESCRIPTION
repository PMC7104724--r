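Package: circptr
Title: Growth Dynamics from Circular Modeling of Prokaryotic Coverage Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates replication activity of bacteria and archaea from
    whole-genome sequencing coverage depth along a circular chromosome.
    Binned depth is treated as weighted angular observations and fitted with
    circular probability distributions (von Mises, cardioid, wrapped Cauchy,
    Jones-Pewsey, linear cardioid, exponential linear cardioid), optionally
    extended for peakedness (Batschelet / inverse Batschelet) or
    mode-invariant skewness. The fitted density yields a probabilistic
    peak-to-trough ratio (pPTR) as a growth proxy and locates the replication
    origin; a mixture extension handles chromosomes with multiple origins
    (wPTR, mwPTR). Includes MAP and Hamiltonian Monte Carlo estimation with
    convergence diagnostics, AIC/BIC/WAIC model selection, likelihood-ratio
    tests, coverage preprocessing (moving median filter, outlier removal),
    Lander-Waterman quality control, and a multinomial coverage simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
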