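Package: kneetemplate
Title: Automated Two-Dimensional Digital Templating for Total Knee
    Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric pipeline for automated two-dimensional preoperative
    templating of total knee arthroplasty from calibrated radiograph
    annotations. Builds femoral and tibial mechanical axes from anatomical
    landmarks, places coronal and sagittal resection lines (9 mm distal
    femoral resection, 10 mm tibial resection with a 2 mm minimum
    lesser-side depth enforced via a 2 degree tibial realignment, and a
    3 degree posterior tibial slope), measures mediolateral and
    anteroposterior bone widths at the resection level, maps widths to
    implant catalogue sizes, and merges per-view size predictions by
    taking the smaller size to avoid overhang. Includes a seeded
    parametric synthetic knee generator with analytic ground truth,
    agreement statistics (exact/accurate taxonomy and quadratic-weighted
    Cohen's kappa), similarity-transform registration against
    postoperative images, mask/landmark file IO, overlay rendering, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
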