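Package: conmap
Title: Voxel-Wise Network Connectedness Mapping with Permutation Cluster
    Inference for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring how strongly each voxel of a resting-state
    fMRI network is coupled to the rest of that network ("connectedness":
    the Fisher-z transformed mean Pearson correlation of a voxel's time
    series with every other network voxel), and for locating where that
    coupling changes between experimental conditions. Implements a
    two-step procedure: step one finds "hotspot" clusters whose
    connectedness differs between paired conditions, with cluster-size
    thresholds calibrated by sign-flip Monte-Carlo permutation of the
    condition labels; step two seeds each hotspot back into a
    network-constrained connectivity contrast to find the "driver"
    clusters behind its change. Includes NIfTI volume handling, a minimal
    residualization chain (simultaneous bandpass and nuisance regression,
    Gaussian smoothing, intensity normalization), seed-based network-mask
    definition with simulation-calibrated cluster thresholds,
    individualized hippocampal/parietal target selection, deterministic
    theta-burst stimulation schedule models, and a multi-subject synthetic
    BOLD study generator with ground-truth effect geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
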