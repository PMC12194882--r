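Package: capforge
Title: Parametric Design and Print-Fidelity QC for Perfusable Microcapillary Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mesh-driven design platform for perfusable three-dimensional
    microcapillary scaffolds fabricated by two-photon lithography. Generates
    porous capillary membranes swept along arbitrary centerline paths
    (imported from CSV or built in: Hilbert space-filling curves, helices),
    with a parametric picture-frame pore grid, circumferential side-pore
    elongation, membrane thickening and subdivision smoothing. Synthesises
    three support systems (polygonal rings with field-of-view seam-aware
    placement, truncated-octahedron lattices with capillary-clearance strut
    culling, and cone supports with capillary subtraction), assembles
    printable chips (flat base, nozzle ports sized for heat-shrink tubing),
    decimates meshes and exports binary STL. Also implements the matching
    quality-control computations: design-versus-print binary-mask
    registration maps, bead-tracking velocimetry, and automated live/dead
    viability counting, together with deterministic synthetic fixture
    generators for all three.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tibble,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
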