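Package: navplast
Title: Reward-Modulated Spiking Plasticity for Valence-Based Spatial Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates hippocampal valence-based spatial learning with a
    spiking feed-forward network of Gaussian place cells driving a ring of
    action neurons (zero-order spike response model with stochastic spike
    emission and N-winner-takes-all lateral connectivity). Feed-forward
    synapses learn through reward-modulated spike-timing-dependent
    plasticity in which dopamine converts eligibility traces into long-term
    potentiation and serotonin into depression, under either a sequential
    (outcome-gated) or a competitive (continuously opposing) weight-change
    rule, with rate-based variants of both. Includes Morris-water-maze and
    reversal-learning task protocols with optogenetic-style perturbation
    schedules, batch simulation with full seed control, and the associated
    behavioural and synaptic metrics (Jensen-Shannon divergence of
    first-reward distributions, coefficient of variation of synaptic
    weights, occupancy and fold-change maps, quadrant dwell times, latency
    and distance statistics).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
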