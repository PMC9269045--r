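Package: gaitsynergy
Title: Quantifying and Modeling Interlimb and Intralimb Gait Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying lower-limb gait coordination and for modeling
    "healthy" gait synergy for assistive-device control. Joint coordination is
    quantified by continuous relative phase (CRP) computed from the Hilbert
    analytic signal, and by a decomposition index (DI) based on a 5 degree/s
    angular-velocity pause criterion for the hip-knee pair. Kinematic
    determinants of disturbed synergy are identified by collinearity-screened
    bidirectional stepwise regression. Interlimb and intralimb synergies are
    modeled by two estimators, a PCA-subspace linear reconstruction
    (complementary limb motion estimation) and a forget-gate LSTM network,
    evaluated under a leave-one-subject-out protocol. A seeded synthetic gait
    generator emulating healthy, stroke and transfemoral-amputee group
    kinematics makes the full pipeline testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, yaml, jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
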