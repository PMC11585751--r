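Package: ki67pi
Title: Ki-67 Proliferation Index Scoring for H-DAB Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the Ki-67 proliferation index (PI) on H-DAB stained
    brightfield regions of interest (ROIs). Images are separated into
    haematoxylin and DAB optical-density channels by colour deconvolution,
    nuclei are segmented with an intensity threshold, Euclidean distance
    transform, peak seeding and marker-controlled watershed, and each
    nucleus is called Ki-67 positive or negative from its DAB staining
    intensity. Includes reader-concordance analytics (pairwise RMSE
    matrices, Bland-Altman limits of agreement, agreement rates, error
    histograms) and a synthetic H-DAB image and reader-study generator
    with pixel-level ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
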