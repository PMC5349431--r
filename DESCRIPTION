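Package: ligenergy
Title: Protein-Ligand Bound-State Interaction Energy for Model Validation
    and Ligand Ranking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the interaction energy of a protein-ligand complex in
    its bound state directly from a deposited or candidate crystallographic
    model, using a semi-empirical pairwise force field of the AutoDock 4
    family (6-12 dispersion/repulsion, directional 10-12 hydrogen bonding,
    Coulomb electrostatics with a distance-dependent dielectric, and a
    Gaussian desolvation term) with Gasteiger-Marsili (PEOE) partial charges
    and polar hydrogens placed at riding positions.  The energy, normalized
    per non-hydrogen ligand atom, classifies complexes as clashing, weakly
    or nonspecifically bound, or unproblematic, and can be combined with a
    real-space density-fit term (RSCC) to re-rank candidate ligand
    identities.  Includes readers for PDB and mmCIF models, ligand selection
    and quality filters, a synthetic mini-complex generator for testing, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
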