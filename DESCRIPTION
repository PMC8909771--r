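Package: arguide
Title: Fiducial Registration, Needle Guidance and Ablation-Margin
    Assessment on Synthetic CT Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for augmented-reality-guided percutaneous
    liver tumor ablation workflows. Provides seeded synthetic CT phantoms
    with non-repetitive skin fiducial constellations and a five-marker
    needle clip; threshold-based organ and marker segmentation; rigid
    point-set co-registration with fiducial and target registration error
    metrics; skin-to-target trajectory planning with alignment feedback
    and depth readout; and post-ablation confirmation that quantifies
    tumor coverage and the residual 5-mm periablational margin with the
    greater-than-90 percent technical-success rule. Volumes are read and
    written as NIfTI or MetaImage, and session records mirror per-target
    clinical report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
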