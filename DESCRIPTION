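Package: l4ei
Title: Excitation-Inhibition Ratio Plasticity in a Layer 4 Spiking Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying feedforward and feedback excitation-inhibition
    (E-I) ratios from voltage-clamp slice electrophysiology, deriving the synaptic
    plasticity factors induced by brief monocular deprivation (thalamocortical
    depression onto excitatory and inhibitory neurons, potentiation of recurrent
    excitation onto inhibition), and testing their circuit-level consequences in a
    conductance-based leaky integrate-and-fire network model of primary visual
    cortex layer 4. Includes synthetic-data generators for every recording
    paradigm (miniature EPSC traces, optogenetically evoked quantal events, paired
    EPSC/IPSC sweep families, LTD amplitude series, FI protocols, and
    minimal-stimulation trials), automated event detection and charge-based ratio
    quantification, paired-seed scenario simulations, Monte-Carlo robustness
    sweeps with firing-rate matching, and grid scans over the two E-I ratio
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
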