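Package: mupoolsim
Title: Motor-Unit Pool Firing, Short-Term Synchronization and Muscle Force Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the isometric force of a rat medial gastrocnemius
    muscle built from a pool of 57 motor units (8 slow, 23 fast
    fatigue-resistant, 26 fast fatigable) with experimentally measured
    contractile and firing properties.  Generates stochastic spike trains
    per unit (uniform inter-pulse-interval jitter around each unit's mean
    rhythmic rate), imposes short-term synchronization by four pulse
    shifting schemes at selectable time windows, and quantifies the effect
    with a binary-train correlation index, a cross-interval
    synchronization index, six force statistics and the mean spectral
    frequency of the force.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
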