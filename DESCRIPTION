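Package: latmirror
Title: Hemispheric Laterality Indices from Statistic Maps and Doppler Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes hemispheric laterality indices (LIs) from volumetric
    task-activation t-statistic maps and from bilateral functional
    transcranial Doppler (fTCD) blood-flow-velocity recordings. Two fMRI
    estimators are provided: the threshold-bootstrap ("toolbox") LI, which
    resamples suprathreshold voxels across an equally spaced grid of t
    thresholds and summarises them by a threshold-weighted trimmed mean with
    a weighted-histogram confidence interval, and the threshold-free
    ("mirror") LI, which flips the right hemisphere onto the left, subtracts
    homologous voxel values and subsamples the resulting difference map.
    fTCD recordings are preprocessed (downsampling, artefact rejection,
    normalisation, heart-cycle integration, epoching, baseline correction,
    trial rejection) and their LI estimated as the side-by-period-of-interest
    interaction of an additive regression model. Individuals are categorised
    as left-, right- or bilaterally lateralised from the 95% confidence
    interval, and between-method agreement is summarised by rank correlation
    with a bootstrap interval. A synthetic-data generator with known ground
    truth supports testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    splines,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
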