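Package: lesionadapt
Title: Lesion-Adaptive PET Segmentation and Method Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded semi-automatic segmentation of FDG PET lesions on SUV
    volumes (fixed SUV2.5/SUV4.0 thresholds, 41% of SUVmax, background-adapted
    A50peak, and majority-vote fusion), lesion-level uptake feature extraction
    (SUVpeak, local background SUV, tumour-to-background ratio, metabolic tumour
    volume), and an exhaustive cross-validated search over prioritised
    two-condition decision rules that pick the preferred segmentation method per
    lesion. Includes baseline machine-learning method selectors, MTV/TMTV
    agreement analysis against a preferred-rating reference, scan quality
    control, NIfTI and CSV input/output, and synthetic phantom and rating-table
    generators so the whole pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    nnet,
    rpart,
    randomForest,
    e1071,
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
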