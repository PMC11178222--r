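Package: qctcalib
Title: Phantom-Based and Phantomless Densitometric Calibration of CT Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative computed tomography (QCT) densitometric
    calibration of single-limb CT scans. Implements classical phantom-based
    calibration (mean Hounsfield units over hydroxyapatite insert regions
    regressed against known equivalent mineral densities) and an automatic
    phantomless alternative that uses the patient's own air, adipose and
    muscle tissues as internal references: a landmark-driven volume of
    interest is built between the femoral head and knee centres, the
    Hounsfield-unit distribution inside it is fitted with a Gaussian kernel
    density, tissue peaks are detected and regressed against reference
    equivalent mineral densities. Includes density-to-Young's-modulus
    material mapping, agreement metrics between two calibrated fields (root
    mean square relative error, point-wise relative differences with
    interquartile-range outlier screening, regression agreement), readers for
    NIfTI volumes and DICOM series, and a synthetic-data generator producing
    calibration phantoms and single-limb thigh volumes with known
    ground-truth calibration lines for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
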