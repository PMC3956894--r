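Package: contactfold
Title: Contact-Assisted Fragment-Assembly Protein Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained de novo protein structure prediction by fragment
    assembly under a hybrid objective that combines knowledge-based statistical
    potentials with a pseudo-energy term derived from predicted residue-residue
    contacts. Provides readers and writers for the standard input formats
    (FASTA, PSIPRED ss2, CASP RR contact lists, PDB), torsion-space chain
    building, structural comparison metrics (RMSD, TM-score, distance-matrix
    error), fragment-library construction with per-position shortlists,
    replica-exchange simulated-annealing sampling with all-at-once or
    sequential contact introduction, model selection by energy or TM-score
    clustering, ensemble model-quality assessment from long-range contact
    satisfaction and mean pairwise TM-score, and a synthetic toy-protein
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
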