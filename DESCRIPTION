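Package: saxsens
Title: Ensemble Modeling of Flexible Proteins Against Small-Angle X-Ray
    Scattering Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Starting from a single protein structure with flexible regions
    (for example an AlphaFold prediction with low-confidence linkers), builds
    a pool of conformers by Monte Carlo sampling of backbone phi/psi torsions
    with hard-sphere clash rejection, computes pair-distance distribution
    functions P(r) and Debye scattering intensities I(q) for each conformer,
    and selects a weighted ensemble whose summed calculated profiles best
    match experimental SAXS data by non-negatively constrained least squares
    (Lawson-Hanson active set). Includes flexible-region detection from
    per-residue confidence values, stride/offset pool reduction with radius
    of gyration histogram diagnostics, adjacent-frame augmentation of
    preselected models, and a staged project pipeline with a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'elements.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'structure-io.R'
    'curves-io.R'
    'flexible-regions.R'
    'saxs-profiles.R'
    'mc-sampler.R'
    'pool-ops.R'
    'nnls.R'
    'ensemble.R'
    'fixtures.R'
    'pipeline.R'
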