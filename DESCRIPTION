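Package: slugforage
Title: Agent-Based Simulation of Foraging Decision, Reward Learning, and
    Addiction-Like Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An agent-based simulator of cost-benefit foraging decisions in a
    generalist predator modeled on the sea slug Pleurobranchaea californica.
    A single forager navigates a toroidal arena of diffusing odor fields,
    learns positive and negative values of prey odor signatures by
    Rescorla-Wagner conditioning, and integrates incentive, satiation, reward
    experience, and pain into an appetitive state that switches turn
    responses between approach and avoidance. A two-neuron homeostatic reward
    circuit produces desensitization, withdrawal, resensitization, and
    craving dynamics when a high-reward, non-nutritive drug item is
    available, supporting selectivity-map, pain-map, and addiction-cycle
    experiments with seeded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
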