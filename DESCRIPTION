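Package: braincase
Title: Single-Subject Normative Comparison of Structural MRI Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compares one subject's regional and voxel-wise gray-matter
    biomarkers against an age-matched normative control cohort using
    single-case statistics (z-scores and the Crawford-Howell modified t-test
    with Benjamini-Hochberg false-discovery-rate correction over a region
    panel), runs the same test voxel-wise on spatially registered modulated
    gray-matter images, and aggregates binarized single-subject atrophy maps
    into group probability overlap maps, region-wise atrophy prevalence,
    disease-burden correlations and longitudinal atrophy rates. Includes
    readers for segmentation statistics tables and NIfTI-1 volumes, and a
    seeded synthetic-data generator for cohorts, biomarker tables and
    3-D gray-matter images with implanted focal atrophy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
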