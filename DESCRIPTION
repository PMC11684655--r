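Package: astroca
Title: Multi-Compartment Astrocyte Calcium Signaling Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based, multi-compartment models of astrocyte
    intracellular calcium signaling under glutamatergic and dopaminergic
    stimulation. Provides compartment-tree morphologies (unipolar, bipolar,
    bifurcated-terminal, and SWC import/export), a detailed twelve-variable
    biophysical compartment model (IP3 receptor and SERCA endoplasmic-reticulum
    fluxes, Na+/Ca2+ exchange, glutamate transport, Na+/K+-ATPase, leak
    currents, membrane potential, and transmitter kinetics), a reduced
    two-variable calcium/IP3 model with nullcline, equilibrium and stability
    analysis, Poisson stimulation protocols, calcium event detection, and
    reproducible frequency- and parameter-sweep experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
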