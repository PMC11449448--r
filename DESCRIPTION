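Package: woundquant
Title: Quantification of Cell Behaviours Driving Epithelial Wound Closure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the three cell behaviours that drive
    re-epithelialisation of wounds in a planar epithelium - cell migration,
    cell shape change and cell division - as spatiotemporal heatmaps in a
    wound-centred frame of reference. Per-cell nematic shape tensors
    (q-tensors) and the radial elongation statistic dQ1, deviation
    velocities of tracked nuclei, and division densities are binned by
    distance-to-wound (Euclidean distance transform, annular bands) and
    time after wounding; replicate movies are combined by tissue-area
    weighting, with signal-to-noise maps, unwounded virtual-wound
    baselines and control-versus-perturbation difference maps. A synthetic
    epithelium simulator with known ground truth (advected Voronoi cells,
    imposed velocity and elongation fields, inhomogeneous Poisson division
    events) supplies test fixtures in place of confocal movies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
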