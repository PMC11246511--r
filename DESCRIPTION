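Package: vertebra3d
Title: 3D Vertebra Shape Reconstruction from Orthogonal Bi-Planar Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the three-dimensional binary shape of individual
    vertebrae from a pair of orthogonal two-dimensional radiograph patches
    (coronal and sagittal) annotated with centroid masks, using a generative
    adversarial network whose generator fuses each view with its centroid
    annotation through non-local self-attention, lifts the fused 2D features
    into a shared 3D frame by orthogonal duplication, and decodes them with a
    3D residual U-Net.  Includes digitally-reconstructed-radiograph (DRR)
    synthesis from labelled CT volumes, a synthetic spine phantom generator,
    VerSe-style case ingestion with spine-level exclusion filtering and
    patient-wise splitting, an integrated training loss combining Dice,
    distance-transform Hausdorff, focal and least-squares adversarial terms,
    alternating adversarial training, per-vertebra reconstruction with spine
    re-assembly, and Dice / 95th-percentile Hausdorff distance / normalised
    surface distance evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
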