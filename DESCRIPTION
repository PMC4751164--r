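Package: aorticroot
Title: Automatic Aortic Root Landmark Detection and Sizing from CTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic detection of aortic-root landmarks for
    transcatheter aortic valve implantation (TAVI) planning from a CT
    angiography volume, a segmented aortic-root surface mesh, and a
    centerline. Detects the sinotubular junction by Fourier-harmonic
    analysis of the unwrapped wall-radius map, the two coronary ostia from
    an outward average-intensity projection map, and the three valvular
    hinge points from the product of a Gaussian-curvature map and
    minimum/maximum intensity inward-the-wall maps; derives sizing
    parameters (annulus plane, center and radius, annulus-to-ostium
    distances, plane angles). Includes a parametric aortic-root phantom
    generator with ground-truth landmarks, and the accuracy statistics
    (paired landmark errors, Bland-Altman, intraclass correlation) used to
    compare automated and manual measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
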