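Package: ttdock
Title: Grid-Free Protein-Ligand Docking by Tensor-Train Global Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-free docking of a flexible ligand into a receptor with
    moveable atoms. The joint conformational space (ligand translation,
    rotation and torsions plus Cartesian coordinates of selected receptor
    atoms) is discretized on a fine grid and the global energy minimum is
    located by tensor-train cross interpolation with maxvol pivoting,
    magnitude maximization of an arccot-transformed energy, and rough
    in-loop Subplex refinement. A post-processing chain deduplicates
    candidate minima, polishes them with box-constrained L-BFGS-B,
    removes symmetry-equivalent duplicates using chemical-digest grouping
    with Hungarian assignment, and reports an energy-sorted spectrum of
    unique minima annotated with INON and EN docking-paradigm indices.
    A reference vacuum force field and deterministic toy-complex
    generators make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    clue,
    digest,
    nloptr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'crc32.R'
    'maxvol.R'
    'tt-core.R'
    'forcefield.R'
    'molecular.R'
    'io.R'
    'dof-space.R'
    'engine.R'
    'store.R'
    'postprocess.R'
    'fixtures.R'
    'ttdock-package.R'
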