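Package: sutureGAT
Title: Joint Suturing Sub-Skill Assessment with Masked Graph Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage joint assessment of six suturing sub-skills from
    per-sub-phase clip features and instrument kinematics. Stage one trains an
    independent sequence model per sub-skill and exports a fixed-length clip
    feature; stage two fuses those features with camera-relative, normalized,
    length-aligned kinematic streams and refines them with a single masked
    graph-attention layer over a prior sub-skill relationship graph, with
    ablation switches for the attention mechanism and the kinematic stream.
    Includes a multi-institution synthetic cohort generator with
    graph-structured cross-sub-skill dependence, leave-one-institution-out
    evaluation with AUC summary tables and attention-map reports, PABAK and
    calibration utilities, and logistic-regression association of skill scores
    with binary clinical outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
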