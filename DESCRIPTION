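Package: levyrnn
Title: Finite-Size Dynamics of Recurrent Networks with Heavy-Tailed Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for discrete-time recurrent neural
    networks whose synaptic weights are drawn from symmetric Levy alpha-stable
    distributions. Provides exact Chambers-Mallows-Stuck sampling of stable
    variates, nonlinear (tanh) and linearized annealed/quenched network
    dynamics with overflow-safe log-magnitude bookkeeping, a Monte-Carlo
    theory of the finite-size quiescent-to-chaotic transition gain,
    QR-based (Benettin) Lyapunov spectra, Kaplan-Yorke attractor dimension,
    participation-ratio dimensionality, and an experiment layer covering
    transition sweeps, maximal-Lyapunov-exponent sweeps, dimensionality
    analysis, mega-synapse ablation, and a delayed-XOR reservoir task.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
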