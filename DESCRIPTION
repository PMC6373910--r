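Package: deltam
Title: Detection-Free Quantification of Receptor Endocytosis in
    Fluorescence Microscopy Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the pharmacological response evoked by agonist
    compounds in time-course fluorescence microscopy images without
    detecting individual objects. Images are band-pass filtered with a
    Laplacian-of-Gaussian kernel at an amplification-optimal scale and
    the response is summarized by the relative increment of the third
    central moment of the filtered intensities over an automatically
    segmented region of interest. Includes a synthetic endosome
    simulation study for validating the discrimination power of the
    statistic, sigmoid time-response curve fitting with goodness-of-fit
    quality control, and a reproducible end-to-end pipeline over TIFF
    stacks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
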