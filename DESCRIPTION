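Package: fragmc
Title: Nested Multipotential Monte Carlo with Fragment-Based Composite
    Energies for Molecular Liquids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sampling engine and analysis toolkit for bulk molecular
    liquids in which inner-loop Metropolis moves generated by a cheap
    classical force field are periodically accepted or rejected against a
    composite many-body-expansion energy: a medium-level full-system term
    plus high-level pairwise corrections for proximate dimers within a
    cutoff. Supports NVT and NpT ensembles, adaptive temperature scaling
    of the generating chain, pluggable energy backends (built-in force
    field, external engine adapter), thermodynamic estimators (density,
    vaporization enthalpy, thermal expansivity, vapor-liquid heat-capacity
    difference, radial distribution functions) with block-averaged
    uncertainties, and extraction of two-level pair-interaction energy
    libraries in extended-XYZ format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'system-model.R'
    'xyz-io.R'
    'potentials.R'
    'external-engine.R'
    'mbe.R'
    'mc-kernel.R'
    'nested-mc.R'
    'estimators.R'
    'rdf.R'
    'pair-library.R'
    'presets.R'
    'config-run.R'
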