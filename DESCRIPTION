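Package: flexscope
Title: Cosserat Rod Simulation of a Flexible Endoscope with Tool-Tissue
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physics core for simulating a virtual flexible endoscope as an
    inextensible, incompressible Cosserat elastic rod with unified bend/twist
    dynamics.  The centreline is kept inextensible by a chain of hard distance
    constraints solved globally as a tri-diagonal banded system (Gaussian
    elimination with partial pivoting), followed by local projection of
    collision constraints with a Coulomb friction approximation.  Includes
    AABB bounding-volume-hierarchy collision detection against triangle
    meshes, mass-spring tetrahedral soft bodies supporting grasping, clipping,
    cutting and diathermy, seeded synthetic scene generators (tortuous rigid
    channel, toy abdomen), trajectory recording/replay, and a surgical
    performance-metric suite (economy of movement, tissue forces, diathermy
    targeting) exported as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
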