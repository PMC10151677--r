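Package: ttedose
Title: Dosimetry of Metal-Port Breast Tissue Expanders Under Megavoltage
    Photon Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale dosimetric characterization of single- and dual-port
    temporary breast tissue expanders (DermaSpan, AlloX2, AlloX2-Pro) for
    post-mastectomy radiotherapy. Provides parametric port templates and
    voxel phantom generators for a wax-slab and a breast-balloon irradiation
    setup, a synthetic CT model with metal-artifact density saturation and
    bloom, the two clinical artifact-handling strategies (threshold-based
    density override and rigid template registration), a voxel Monte Carlo
    photon transport engine (Woodcock delta tracking, collision-kerma
    scoring) together with an analytic primary-beam raytracer, and the
    comparison machinery: depth-dose and crossline profiles, gamma index,
    DVH parameters (D1/D10/mean) and port-effect difference reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tools,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
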