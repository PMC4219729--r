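Package: ionpocket
Title: Continuum Electrostatics of Divalent-Ion and Peptide Binding to
    Protein Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the binding of a small divalent cation (such as Be2+)
    and short peptides to an acidic protein pocket of the kind found in the
    MHC class II peptide-binding groove. Provides a finite-difference
    Poisson solver in a two-dielectric continuum, electrostatic-potential
    ranked ion binding-site prediction, MM-PBSA-style binding free energy
    decomposition for alternative ion/peptide binding orders, elastic-network
    Langevin conformational sampling, trajectory RMSD and pocket-width
    analytics, and single-conformer continuum-electrostatics pKa and
    Monte Carlo titration. Includes seeded synthetic-structure generators
    (acidic-pocket mini-receptors, class-structured 10-mer peptides, Born
    fixtures, trajectories with known ground truth) for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
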