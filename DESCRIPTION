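Package: calcmorph
Title: Morphometry of Intracranial Arterial Calcification from CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of intracranial internal carotid artery
    calcification (iICAC) from computed tomography. Calcified voxels are
    segmented by Hounsfield-unit windowing (130-500 HU) inside a supplied
    artery mask, converted to a watertight triangle-mesh surface model, and
    summarised by total surface area S and a per-face thickness T estimated
    as the shortest centroid-to-centroid distance between faces whose
    normals oppose each other. Thickness values are weighted by their
    alignment with the local artery-wall normal direction and summarised as
    a weighted 97th-percentile representative thickness. The package also
    provides voxel phantom generators with analytic ground truth, a
    resolution-reproducibility harness, a synthetic cohort generator, and
    the cohort regression stage (standardised linear models of regional
    brain volumes on S and T with variance inflation factors and
    Benjamini-Hochberg false-discovery-rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    tibble,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
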