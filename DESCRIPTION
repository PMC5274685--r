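Package: cartiqus
Title: Quantitative Ultrasound and Micro-CT Morphometry for Cartilage and
    Trabecular Bone Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates high-frequency pulse-echo ultrasound scans of
    articular cartilage and binary micro-CT trabecular bone volumes with
    known ground truth, detects surface and cartilage-bone interface
    echoes on radiofrequency A-lines, and computes the quantitative
    ultrasound panel (ultrasound roughness index, surface and interface
    reflection coefficients, cartilage thickness) together with the
    standard trabecular morphometry panel (BV/TV, Tb.N, Tb.Th, Tb.Sp,
    connectivity density, structure model index). Two-group cohorts are
    compared parameter by parameter with an exact Mann-Whitney U test,
    reproducing the design of early-osteoarthritis ovariectomy studies
    end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
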