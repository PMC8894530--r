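Package: zirconomics
Title: Noise Sensitivity of Radiomic Features from Low-Count Immuno-PET
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how Poisson count noise degrades the precision and
    accuracy of PET radiomic features under the low signal-to-noise conditions
    typical of 89Zr-immuno-PET. Provides a synthetic phantom generator with
    count-split replicates at 50% and 25% of full counts (binomial thinning of
    voxelwise Poisson counts, the statistical analogue of alternate list-mode
    event splitting), an IBSI-style radiomic feature engine covering 458
    features in ten families (local intensity, intensity statistics, intensity
    histogram, intensity-volume histogram, GLCM, GLRLM, GLSZM, GLDZM, NGTDM,
    NGLDM) with SUV conversion, 2 mm isotropic resampling and fixed-bin-width
    discretisation, and a robustness module computing per-feature two-way
    absolute-agreement intraclass correlation coefficients (precision) and
    similarity distance metrics (noise-induced bias) across replicates, with
    lesion subsampling, four-level categorisation and Fisher's exact
    comparison of category distributions between noise levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
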