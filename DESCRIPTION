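Package: pupavision
Title: Machine-Vision Sexing of Melon Fly Pupae from Time-Series Microscope Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Image-analysis pipeline that identifies male and female pupae of the
    melon fly (Zeugodacus cucurbitae) from daily stereomicroscope images. The
    pipeline normalizes wide-range three-channel images to 8 bits, extracts the
    pupal body by Otsu thresholding of the HSV saturation channel followed by hole
    filling and morphological opening, pose-normalizes the body via a minimum
    enclosing ellipse and its circumscribed rectangle, resamples to a fixed
    2800 x 1300 standard frame, screens a 5 x 5 grid of cells for day-over-day
    texture change, detects the elongated dark pectinate setae that appear on the
    tail of male pupae two days before eclosion, and evaluates the resulting sex
    calls against eclosion outcomes in a contingency table. A seeded synthetic
    pupal-image generator with known ground truth makes the whole pipeline
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    cluster,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
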