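Package: epimapr
Title: Epicardial Electrogram Mapping and Ex Vivo Perfusion Analytics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for unipolar epicardial electrograms (UEG)
    recorded on rectangular multielectrode grids during ex vivo working-heart
    perfusion, together with trend analytics for hourly blood-panel and
    hemodynamic time series. Provides a kinematic wavefront simulator with
    known ground truth, zero-phase Butterworth band-pass preprocessing, beat
    segmentation around pacing stimuli, activation-time detection at the
    minimum of the signal derivative, isochrone activation maps, two-point and
    plane-fit wave-propagation-velocity estimation with restitution summaries
    across pacing rates, and per-analyte slope, excursion, cardiac-output
    deterioration and homeostasis-duration statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, Preprocessing
RoxygenNote: 7.3.3
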