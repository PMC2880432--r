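Package: hmecsim
Title: Lattice Agent-Based Simulation of Mammary Epithelial Cell Outgrowth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the clonal outgrowth of variant human mammary epithelial
    cells (vHMEC) from normal, finite-lifespan HMEC cultures on a pixel lattice
    with exclusive occupancy. Agents divide while adjacent space is available,
    divide compressed down to a minimum footprint when crowded, convert
    permanently to a senescent state at a per-class division limit, and are
    excluded at subculture because senescent cells do not reattach. Includes a
    serial-passaging driver (replate at 80% saturation), an exponential
    radiation-induced senescence module with per-class dose-response fitting,
    and an analysis layer: population-doubling bookkeeping, growth-plateau
    detection, the inverse power law linking plateau width to the initial
    variant fraction, and replicate dispersion statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
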