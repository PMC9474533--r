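Package: cvrkit
Title: Cerebrovascular Reactivity Mapping from Breath-Hold BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of breath-hold hypercapnia BOLD fMRI for
    cerebrovascular reactivity (CVR) mapping. Builds an end-tidal CO2
    (PetCO2) regressor from raw capnograph traces (end-tidal peak
    detection, resampling to the acquisition grid, quadratic detrending,
    convolution with a canonical hemodynamic response function), fits a
    voxel-wise general linear model to obtain CVR maps in percent BOLD
    signal change per mmHg of PetCO2, summarises CVR as tissue medians
    with lesion exclusion, computes normalised tissue volumes, and runs a
    longitudinal cohort statistical battery (repeated-measures ANOVA,
    paired and unpaired t-tests, Pearson correlations with Fisher
    z-transforms, Lilliefors-type normality screening) together with
    group-level voxel-wise permutation inference using threshold-free
    cluster enhancement (TFCE). A synthetic-data module generates
    phantoms, capnograph traces, BOLD series, lesion masks and whole
    cohorts with known ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
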