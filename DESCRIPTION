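Package: placeboconn
Title: Resting-State Connectivity Prediction of Placebo Antidepressant Response
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for baseline resting-state functional
    connectivity analysis of placebo (sham stimulation) antidepressant
    response. Implements CONN-style nuisance regression (motion, scrubbing,
    aCompCor or global-signal regression), linear detrending, hyperbolic
    tangent despiking and band-pass filtering; voxelwise global brain
    connectivity and rostral anterior cingulate seed-based Fisher-z
    functional connectivity maps; group one-sample t-maps with sign-flip
    cluster-extent family-wise-error inference; and elastic-net
    leave-one-out prediction of Hamilton Depression Rating Scale percent
    change with permutation inference. Ships a synthetic BOLD cohort
    generator with planted seed-target coupling so every stage can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: glmnet, jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
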