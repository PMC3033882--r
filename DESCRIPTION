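Package: surfmorph
Title: Surface-Based Morphometry for Single-Subject Detection of Cortical Malformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertex-wise normative modelling on triangulated cortical surface
    meshes for detecting focal cortical malformations in single subjects.
    Reads and writes FreeSurfer binary surfaces, 'curv' overlays and ASCII
    labels; computes cortical thickness, gray/white matter intensity contrast,
    and discrete mean curvature; smooths overlays on the mesh with an
    FWHM-calibrated iterative kernel; z-scores individual subjects against a
    healthy control cohort (with leave-one-out scoring of the controls
    themselves) and extracts area-thresholded supra-threshold clusters; and
    evaluates detection performance with categorical and area-based
    sensitivity/specificity, ROC curves, threshold-by-smoothing parameter
    sweeps, and intracranial-electrode classification. A synthetic-cohort
    generator produces icosphere meshes, spatially correlated normative
    overlays, and implanted focal lesions so the entire pipeline can be
    exercised and validated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
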