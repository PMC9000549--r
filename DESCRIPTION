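Package: hvgate
Title: Trajectory Analyses of Voltage-Gated Proton Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of the
    Hv1 voltage-gated proton channel (and similar four-helix voltage-sensor
    domains): per-frame continuous water-wire detection with occupancy
    statistics, geometric hydrogen-bond and salt-bridge time series with
    partner-switching summaries, helix and sidechain z-axis kinematics
    relative to the four-helix center, a deterministic sphere-fitting pore
    radius profiler, peptide isoelectric-point helpers, and a synthetic
    trajectory generator that plants ground truth (wire frames, helix
    shifts, contact schedules) so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    seqinr,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
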