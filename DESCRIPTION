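Package: sitevec
Title: Binding-Site Vectors for Pocket Shape and Electrostatics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Describes macromolecular binding pockets by a geodesic fan of
    rays ("binding site vectors") cast from an interior anchor point toward
    the vertices of a subdivided icosahedron, each ray truncated at the
    first van der Waals atomic surface it meets and labelled with that
    atom's partial charge.  Provides shape, charge and combined RMSD
    metrics between descriptors, ensemble-weighted comparison of
    conformational ensembles, exemplar clustering by affinity propagation,
    average-linkage similarity trees, and a binary geometric criterion for
    testing whether a ligand pose fits inside a pocket.  Includes
    deterministic generators of synthetic cavities with analytically known
    geometry for validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ape,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
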