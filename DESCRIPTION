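Package: lasernav
Title: Multimodal Fiducial Registration and Accuracy Simulation for
    OCT-Guided Laser Bone Marking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses an image-guided laser labeling workflow
    for the middle cranial fossa: generation of paired synthetic cone-beam CT
    (CBCT) and optical coherence tomography (OCT) phantom volumes with known
    ground truth, sub-voxel detection of spherical titanium fiducial markers
    in both modalities, exhaustive distance-pattern correspondence matching,
    closed-form rigid (Kabsch) registration with fiducial and target
    registration error bookkeeping, silhouette-based planning of target
    points outlining the internal auditory canal on the bone surface, laser
    workspace and incidence-angle constraint checking, a crater-depth
    ablation model, and a seeded Monte-Carlo accuracy-verification study
    that closes the loop by re-imaging verification spheres placed at the
    ablated sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
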