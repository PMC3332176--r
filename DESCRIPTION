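Package: dermseg
Title: Wavelet-Domain Fuzzy Clustering Segmentation of Dermoscopic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of pigmented skin lesions in dermoscopic RGB images
    by clustering in the 2-D discrete wavelet transform domain. Implements
    wavelet-feature K-means (WK-Means), wavelet-feature fuzzy C-means (W-FCM)
    and a fuzzy-inference cluster-count preselection variant (W-CPSFCM) that
    chooses the number of clusters automatically from image intensity range
    and size, together with a statistical region merging (SRM) baseline,
    ROC/AUC evaluation by threshold sweep, and a deterministic synthetic
    lesion generator with exact ground-truth masks for validation.
License: MIT
Encoding: UTF-8
Imports:
    png,
    jpeg,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
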