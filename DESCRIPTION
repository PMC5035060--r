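Package: primedock
Title: Template-Based Modeling of Protein-RNA Complex Structures
Version: 0.1.0
Authors@R:
    person("PRIME", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for template-based rigid-body docking of protein-RNA
    binary complexes. Curates a non-redundant library of binary
    protein-RNA complexes from coordinate files, finds templates for a
    target protein/RNA pair by structural alignment (a TM-score protein
    aligner and a self-normalized RNA backbone aligner) or by sequence
    alignment, builds models by superposing the target monomers onto the
    template, and evaluates models with interaction RMSD, ligand RMSD and
    CAPRI-style quality classes. Includes a deterministic synthetic
    structure generator so the whole pipeline is testable without
    downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
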