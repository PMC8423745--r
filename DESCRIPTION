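Package: occlustress
Title: Dynamic Occlusal Contact-Stress Simulation from Recorded Jaw Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dynamic occlusal contact stress on dental arches driven
    purely by recorded jaw kinematics (displacement-boundary-condition contact
    analysis). High-rate incisal-point displacement traces and low-rate
    per-plane rotation angles extracted from landmark marker pairs are fused
    into a time-segmented rigid trajectory of the mandibular dentition; a
    quasi-static elastic-foundation (Winkler) penalty contact solver then maps
    signed gaps, contact pressure, Coulomb frictional shear and maximum
    principal contact stress onto the moving arch at every trajectory segment.
    Includes mesh I/O (STL, PLY, OBJ, VTK export), Laplacian mean-filter
    smoothing, FDI tooth labelling, virtual occlusal carving, a parametric
    synthetic dentition generator with plantable balancing-side interferences,
    mirror-trace symmetric-excursion experiments, and carve-then-rerun virtual
    occlusal-adjustment experiments with per-tooth stress reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
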