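Package: triphasic
Title: Evoked Spiking Dynamics in Paired Somatosensory and Motor Cortex Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing peristimulus spiking dynamics evoked by brief
    peripheral photostimulation, recorded simultaneously in hand/forelimb
    primary somatosensory (S1) and motor (M1) cortex. Implements peristimulus
    time histogram (PSTH) construction, z-score based detection of
    stimulus-responsive units, extraction of triphasic response parameters
    (short-latency peak, post-peak suppression, post-inhibitory rebound),
    laminar depth profiling, optogenetic tagging of parvalbumin (PV)
    interneurons, paired-pulse recovery curves, pathway propagation-speed
    estimates, and partial-silencing effect quantification. Includes a fully
    parameterised synthetic-cohort generator (inhomogeneous Poisson spike
    trains sampled by thinning) that retains ground truth for
    parameter-recovery testing, so every stage of the pipeline is verifiable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
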