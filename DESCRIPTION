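Package: fluorkin
Title: Kinetic Modelling and SUV Normalization for Sodium [18F]Fluoride PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification workflow for dynamic sodium [18F]fluoride PET of
    skeletal lesions in spondyloarthritis. Implements calibration of
    image-derived input functions against venous blood samples, the
    irreversible two-tissue compartment (2t3k) model with net influx rate
    Ki = K1*k3/(k2+k3) fitted by bounded weighted nonlinear least squares,
    Patlak graphical analysis as an internal cross-check, standardized
    uptake values under body-weight, lean-body-mass (Janmahasatian), body
    surface area and skeletal-volume normalization, spherical fixed-volume
    VOI metrics (SUVmax, SUVpeak, SUVmean) on voxel patches, and the
    comparative statistics used to evaluate simplified metrics against Ki
    (coefficient of variation, group-mean-normalized Levene test,
    weight-group t-tests, Pearson R2 with Fisher-z intervals, Williams'
    test for dependent overlapping correlations, longitudinal ratio
    analysis, Bland-Altman agreement). A synthetic-data generator emulates
    the cohort, 25-frame dynamic schedule, venous sampling, lesion kinetics
    and static voxel patches, so the whole pipeline is testable without
    scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
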