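Package: dcecad
Title: Automated Breast Lesion Detection in Dynamic Contrast-Enhanced MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated computer-aided detection (CAD) pipeline for enhancing
    breast lesions in multi-phase dynamic contrast-enhanced MRI (DCE-MRI)
    axial slices. The pipeline crops the breast region from the pre-contrast
    scan, enhances the second and third post-contrast subtraction images
    (exponential-distribution CLAHE followed by an alternating sequential
    morphological filter), segments enhancing candidate regions by four-level
    multilevel Otsu thresholding and intersection across the two phases, and
    reduces false positives in two stages: geometric rules (minimum size,
    maximum eccentricity) followed by supervised classification of gray-level
    co-occurrence texture and ring-contrast features against mirrored
    contralateral control regions, using a feed-forward neural network and a
    Gaussian-kernel support vector machine with SMOTE balancing. Includes a
    seeded synthetic phantom generator with known ground truth, ReliefF
    feature weighting, sequential backward feature elimination, ROC/AUC
    machinery, and exact-conditional and mid-p McNemar classifier comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    stats,
    utils,
    jsonlite,
    png,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
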