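Package: forelimbkin
Title: Joint Coordinate System Kinematics of the Rodent Forelimb from
    Biplanar Videoradiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for reconstructing and analysing three-dimensional
    skeletal kinematics of the rodent forelimb from marker trajectories or
    biplanar videoradiographic projections.  Implements rigid-body pose
    estimation from bone-fixed markers (SVD/Kabsch), Euler ZYX joint
    coordinate system (JCS) decomposition for a hierarchical
    humerus-ulna-radius chain, 11-parameter direct linear transformation
    (DLT) camera calibration and two-view triangulation, stance/swing
    segmentation of walking trials from a distal-ulna landmark,
    percent-of-cycle normalisation with 5-percent-bin ensemble averaging,
    joint excursion summaries, and a marker-based gold-standard
    accuracy/precision framework.  A forward-kinematic gait simulator
    generates ground-truthed synthetic trials so that every stage of the
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
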