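Package: moldock
Title: Cavity Mapping, Empirical Scoring and Genetic-Algorithm Ligand Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fast docking toolkit for placing small-molecule ligands into
    protein or nucleic-acid binding sites. Provides binding-site definition by
    reference-ligand and two-probe-sphere cavity mapping, an empirical composite
    scoring function (van der Waals, polar, optional desolvation, ligand
    dihedral terms) with optional grid precalculation, a staged genetic
    algorithm / Monte Carlo / Simplex pose search, restraint-based biased
    docking (pharmacophore tolerance spheres, tethered substructure templates,
    cavity containment, distance restraints), symmetry-aware RMSD, SD-file
    utilities, virtual-screening enrichment metrics, and synthetic toy systems
    with known optima for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, igraph, bio3d, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
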