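Package: oligotraj
Title: Contact, Oligomerization and Binding-Kinetics Analysis of
    Peptide-Inhibitor Simulation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses molecular-simulation trajectories of short amyloidogenic
    peptides in the presence of an inhibitor protein. Detects residue-residue
    heavy-atom contacts under periodic boundary conditions, partitions peptides
    into oligomers, labels inhibitor-complexed species, builds two-dimensional
    potential-of-mean-force surfaces over contact counts, computes survival-time
    correlation functions and residence times of inhibitor-bound peptides,
    ensemble-averaged residue-level contact-probability maps, and Kabsch-aligned
    RMSD/RMSF structural metrics. Includes seeded synthetic-trajectory
    generators (two-state Markov binding with geometric placement, constructed
    oligomer scenes, and a Brownian bead-chain toy simulator) that provide exact
    ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
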