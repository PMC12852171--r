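Package: tcombat
Title: Transferable ComBat Harmonization for Multisite Imaging Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Empirical-Bayes ComBat harmonization of multisite feature
    matrices (e.g. voxel-wise fractional anisotropy or mean diffusivity
    maps) with a transferable variant: harmonization parameters fitted on a
    training cohort are saved to a portable plain-text archive and applied
    unchanged to new subjects from known sites. Includes the evaluation
    toolkit used to judge harmonization quality (voxel- and ROI-wise
    site-difference rates, the proportion-within-full-ComBat metric, the
    distribution overlap index), Monte-Carlo subsampling experiment
    drivers, a two-site synthetic data generator with known ground truth,
    and NIfTI volume/mask bridging utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sva
Config/testthat/edition: 3
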