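Package: ispneuron
Title: Inhibitory Synaptic Plasticity and Flexible Receptive Fields in a
    Conductance-Based Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a single conductance-based leaky integrate-and-fire
    neuron driven by tuned excitatory afferents and two plastic inhibitory
    populations.  Natural stimulation is generated as an Ornstein-Uhlenbeck
    modulated inhomogeneous Poisson process organised in signal groups; brief
    pulse stimuli probe transient (phasic) and steady-state (tonic) responses.
    Three online inhibitory plasticity rules are provided (Hebbian,
    homeostatic synaptic scaling, and anti-Hebbian with an exponentially
    decaying learning rate) together with their mean-field fixed points,
    input/output correlation metrics, and experiment drivers for training,
    inhibitory gain modulation, population deactivation with compensatory
    rate adjustment, and pulse sweeps.  The integration core is written in
    C++ for speed; reference implementations in pure R serve as independent
    oracles in the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
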