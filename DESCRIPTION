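Package: burstfield
Title: Neural Field Simulation of Anesthetic Burst Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates spatiotemporal burst suppression on a two-dimensional
    toroidal cortical sheet with a conductance-based excitatory/inhibitory
    neural field model. Post-synaptic potentials follow bi-exponential
    kinetics whose amplitudes and decay times are modulated by isoflurane
    concentration through Hill equations, cortico-cortical activity
    propagates by a damped wave equation, and a slow activity-dependent
    synaptic resource depletion/recovery system generates quasi-periodic
    bursting under deep anesthesia. Includes spatiotemporally filtered
    stochastic extracortical drive, concentration ramp protocols, Welch
    spectral analysis with grid averaging, burst-peak detection with
    inter-burst-interval statistics, and patch-heterogeneity and
    connectivity-scale experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
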