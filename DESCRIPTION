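Package: fibscreen
Title: Structure-Based Screening of Amyloid Fiber Binding Compounds
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering small molecules that bind the flat,
    repetitive surface of amyloid fibers. Builds idealized beta-sheet fiber
    models (in-register parallel, antiparallel, and sheared out-of-register
    stand-ins), prepares and filters screening libraries of flat aromatic
    compounds, generates near-native ligand conformer ensembles, docks
    ligands onto the lysine-rail groove with a component-wise interaction
    energy (Lennard-Jones, hydrogen bonding, electrostatics, optional
    solvation), applies post-docking hard filters and component-wise
    top-fraction selection with shape-complementarity ranking, evaluates
    poses against a geometric pharmacophore (hydrogen-bond distance and
    angle windows, aromatic stacking windows, contacts across adjacent
    strands), and fits apparent dissociation constants to NMR titration
    data under a 1:N monomers-per-site ligand-depletion binding model.
    Includes MTT viability rescue normalization and group comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    ChemmineOB,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'binding.R'
    'ligand.R'
    'conformers.R'
    'fiber.R'
    'energy.R'
    'dock.R'
    'fibscreen-package.R'
    'filter.R'
    'pharmacophore.R'
    'fixtures.R'
    'geometry.R'
    'library.R'
    'residue-templates.R'
    'screen.R'
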