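Package: vessel3d
Title: Intravascular OCT and CTCA Segmentation with 3D Coronary Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis toolkit for coronary artery imaging. Segments
    lumen and adventitia borders on polar intravascular OCT frames (guidewire
    artifact removal, bilateral denoising, fast-marching minimal paths,
    standard-deviation filtering with Frangi vesselness), detects metallic and
    bioresorbable stent struts (shadow/slope scan-line criteria with DBSCAN
    clustering and a morphological rule chain), segments CT coronary
    angiography volumes (multiscale vesselness, minimum-cost-path centerlines,
    seed-calibrated sigmoidal weight functions, 3D level sets, stent
    localization), fuses 2D contours and strut clouds onto a 3D centerline
    with rotation-minimizing frames and lofted surface meshes, and computes
    quantitative vessel and stent metrics (areas, plaque burden, malapposition,
    restenosis, fracture flags). Ships seedable synthetic phantom generators
    with exact ground truth so every stage is testable without clinical data,
    plus bookkeeping utilities for patch-based plaque-classifier datasets and
    architecture specifications.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
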