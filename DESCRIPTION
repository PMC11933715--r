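Package: muscleVolume
Title: Muscle Volume Estimation from Segmented Label Maps
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies skeletal muscle volume from 3D label maps of
    segmented muscles (for example axial MRI segmentations stored as
    NIfTI-1). Computes per-slice anatomical cross-sectional areas (ACSA),
    resamples them onto a 101-point profile over relative muscle length,
    locates the maximal ACSA, and implements two time-efficient volume
    estimators against the slice-by-slice reference: the shape-factor
    method (volume = p * length * ACSA at the cohort-average peak
    location) and the five-slice truncated-cone (frustum) method.
    Agreement between estimators and the reference is assessed with
    Bland-Altman statistics. A voxelized phantom generator with
    closed-form area profiles and volumes provides ground truth for
    validation and cohort simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'agreement.R'
    'profile.R'
    'estimators.R'
    'phantoms.R'
    'io.R'
    'muscleVolume-package.R'
    'pipeline.R'
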